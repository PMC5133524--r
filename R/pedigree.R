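#' Simulate extended pedigrees
#'
#' Generates a set of multi-generation extended families of the kind found in
#' family studies of blood pressure: each family starts from a founder couple,
#' every couple has `1 + Poisson(mean_offspring - 1)` children (so the mean
#' sibship size is `mean_offspring` and no couple is childless), and every
#' child in a non-terminal generation marries a new founder who joins the
#' pedigree with both parents missing.
#'
#' @param n_families number of families (>= 1).
#' @param n_generations number of generations (>= 2).
#' @param mean_offspring mean number of children per couple (>= 1).
#' @param seed integer seed; the output is reproducible byte-for-byte.
#' @return a `data.frame` with columns `family_id`, `individual_id`,
#'   `father_id`, `mother_id` (NA for founders) and `sex`
#'   (`"male"`/`"female"`), parents always preceding their children.
#' @examples
#' ped <- simulate_pedigree(2, 3, 3, seed = 1)
#' table(ped$family_id)
#' @export
simulate_pedigree <- function(n_families, n_generations, mean_offspring, seed) {
  n_families <- assert_count(n_families, "n_families", min = 1L)
  n_generations <- assert_count(n_generations, "n_generations", min = 2L)
  assert_scalar_number(mean_offspring, "mean_offspring", min = 1)
  seed <- assert_count(seed, "seed", min = 0L)

  with_seed(seed, {
    rows <- vector("list", n_families)
    for (f in seq_len(n_families)) {
      fam <- sprintf("FAM%03d", f)
      counter <- 0L
      new_id <- function() {
        counter <<- counter + 1L
        sprintf("%s_I%04d", fam, counter)
      }
      recs <- list()
      add <- function(id, father, mother, sex, gen) {
        recs[[length(recs) + 1L]] <<- data.frame(
          family_id = fam, individual_id = id,
          father_id = father, mother_id = mother,
          sex = sex, generation = gen, stringsAsFactors = FALSE)
      }
      f0 <- new_id(); m0 <- new_id()
      add(f0, NA_character_, NA_character_, "male", 1L)
      add(m0, NA_character_, NA_character_, "female", 1L)
      couples <- list(c(f0, m0))
      for (g in seq_len(n_generations - 1L)) {
        next_couples <- list()
        for (cp in couples) {
          n_kids <- 1L + stats::rpois(1L, max(mean_offspring - 1, 0))
          for (k in seq_len(n_kids)) {
            kid <- new_id()
            sex <- if (stats::runif(1) < 0.5) "male" else "female"
            add(kid, cp[1L], cp[2L], sex, g + 1L)
            if (g + 1L < n_generations) {
              sp <- new_id()
              sp_sex <- if (sex == "male") "female" else "male"
              add(sp, NA_character_, NA_character_, sp_sex, g + 1L)
              next_couples[[length(next_couples) + 1L]] <-
                if (sex == "male") c(kid, sp) else c(sp, kid)
            }
          }
        }
        couples <- next_couples
      }
      rows[[f]] <- do.call(rbind, recs)
    }
    ped <- do.call(rbind, rows)
    rownames(ped) <- NULL
    validate_pedigree(ped)
    ped
  })
}

#' Validate pedigree invariants
#'
#' Checks that every named parent exists within the same family with the
#' right sex, that the parent graph is acyclic, and that individual ids are
#' unique.  Called internally by every consumer of a pedigree.
#'
#' @param ped pedigree data.frame (see [simulate_pedigree()]).
#' @return the pedigree, invisibly, with individuals in an order where
#'   parents precede children.
#' @export
validate_pedigree <- function(ped) {
  need <- c("family_id", "individual_id", "father_id", "mother_id", "sex")
  if (!is.data.frame(ped) || !all(need %in% names(ped)))
    stop_param("pedigree must have columns ", paste(need, collapse = ", "))
  if (nrow(ped) == 0L) stop_param("pedigree is empty")
  if (anyDuplicated(ped$individual_id))
    stop_invariant("duplicated individual_id in pedigree")
  idx <- stats::setNames(seq_len(nrow(ped)), ped$individual_id)
  for (col in c("father_id", "mother_id")) {
    p <- ped[[col]]
    known <- !is.na(p)
    if (any(known & !(p %in% ped$individual_id)))
      stop_invariant("parent id not present in pedigree: ",
                     paste(utils::head(p[known & !(p %in% ped$individual_id)]),
                           collapse = ", "))
    same_fam <- ped$family_id[idx[p[known]]] == ped$family_id[known]
    if (!all(same_fam))
      stop_invariant("parent assigned across families")
  }
  fa <- idx[ped$father_id]; mo <- idx[ped$mother_id]
  if (any(!is.na(fa) & ped$sex[fa] != "male") ||
      any(!is.na(mo) & ped$sex[mo] != "female"))
    stop_invariant("parent sex inconsistent with father/mother role")
  ord <- pedigree_order(ped)   # errors if cyclic
  ## keep the caller's row order when parents already precede children
  fa <- unname(idx[ped$father_id]); mo <- unname(idx[ped$mother_id])
  pos <- seq_len(nrow(ped))
  already <- all(fa < pos, na.rm = TRUE) && all(mo < pos, na.rm = TRUE)
  if (already) invisible(ped) else invisible(ped[ord, , drop = FALSE])
}

## Topological order (parents before children); errors on cycles.
pedigree_order <- function(ped) {
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$individual_id)
  fa <- unname(idx[ped$father_id]); mo <- unname(idx[ped$mother_id])
  depth <- rep.int(NA_integer_, n)
  depth[is.na(fa) & is.na(mo)] <- 0L
  changed <- TRUE
  while (anyNA(depth) && changed) {
    changed <- FALSE
    todo <- which(is.na(depth))
    for (i in todo) {
      df <- if (is.na(fa[i])) 0L else depth[fa[i]]
      dm <- if (is.na(mo[i])) 0L else depth[mo[i]]
      if (!is.na(df) && !is.na(dm)) {
        depth[i] <- max(df, dm) + 1L
        changed <- TRUE
      }
    }
  }
  if (anyNA(depth))
    stop_invariant("pedigree contains a cycle (an individual is its own ancestor)")
  order(depth, seq_len(n))
}

#' Identify pedigree founders
#'
#' Founders are exactly the individuals with both parents missing.
#'
#' @param ped pedigree data.frame.
#' @return character vector of founder individual ids.
#' @export
founders <- function(ped) {
  ped$individual_id[is.na(ped$father_id) & is.na(ped$mother_id)]
}

#' Write / read a PLINK FAM-style pedigree file
#'
#' Six whitespace-separated columns: family, individual, father, mother,
#' sex (1 = male, 2 = female), phenotype (always 0 here).  Missing parents
#' are coded `0`.
#'
#' @param ped pedigree data.frame.
#' @param path output file.
#' @return `write_fam` returns `path` invisibly; `read_fam` returns a
#'   pedigree data.frame.
#' @export
write_fam <- function(ped, path) {
  validate_pedigree(ped)
  out <- data.frame(
    fid = ped$family_id, iid = ped$individual_id,
    pat = ifelse(is.na(ped$father_id), "0", ped$father_id),
    mat = ifelse(is.na(ped$mother_id), "0", ped$mother_id),
    sex = ifelse(ped$sex == "male", 1L, 2L),
    phe = 0L)
  utils::write.table(out, path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = " ")
  invisible(path)
}

#' @rdname write_fam
#' @export
read_fam <- function(path) {
  raw <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("fid", "iid", "pat", "mat", "sex", "phe"))
  ped <- data.frame(
    family_id = as.character(raw$fid),
    individual_id = as.character(raw$iid),
    father_id = ifelse(raw$pat == "0", NA_character_, as.character(raw$pat)),
    mother_id = ifelse(raw$mat == "0", NA_character_, as.character(raw$mat)),
    sex = ifelse(raw$sex == 1L, "male", "female"),
    stringsAsFactors = FALSE)
  validate_pedigree(ped)
  ped
}
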