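#' Build a partial diallel crossing design within a group of parents
#'
#' Enumerates the crosses of a partial diallel in which every parent of a
#' group is mated to every other parent of the same group. With reciprocals
#' each ordered dam x sire pair is a distinct cross, so `n` parents give
#' `n * (n - 1)` crosses and every parent acts `n - 1` times as dam and
#' `n - 1` times as sire. Selfing is excluded by default (the study species
#' is self-incompatible).
#'
#' @param parents character or integer vector of distinct parent ids.
#' @param reciprocals logical; keep both A x B and B x A (default `TRUE`).
#' @param selfing logical; allow A x A crosses (default `FALSE`).
#' @param group optional group label attached to every cross.
#' @return a data frame of class `diallel_crosses` with columns `dam`,
#'   `sire`, and `group`.
#' @examples
#' build_partial_diallel(letters[1:5])  # 20 crosses
#' @export
build_partial_diallel <- function(parents, reciprocals = TRUE, selfing = FALSE,
                                  group = NA_character_) {
  parents <- as.character(parents)
  if (length(parents) < 2L)
    stop("a diallel needs at least 2 parents", call. = FALSE)
  if (anyDuplicated(parents))
    stop("duplicate parent ids in diallel group", call. = FALSE)
  grid <- expand.grid(dam = parents, sire = parents,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (!selfing) grid <- grid[grid$dam != grid$sire, , drop = FALSE]
  if (!reciprocals) {
    # keep one ordered member per unordered pair (dam < sire lexicographically)
    keep <- grid$dam < grid$sire | grid$dam == grid$sire
    grid <- grid[keep, , drop = FALSE]
  }
  grid$group <- group
  rownames(grid) <- NULL
  class(grid) <- c("diallel_crosses", "data.frame")
  grid
}

#' Assign family identifiers to crosses
#'
#' Reciprocal crosses (A dam x B sire and B dam x A sire) produce full sibs
#' and are treated as one family. The family id is the lexicographically
#' sorted parent pair joined with "x", which is deterministic and
#' independent of cross order.
#'
#' @param crosses data frame with `dam` and `sire` columns.
#' @return the same data frame with a `family` column added.
#' @export
assign_families <- function(crosses) {
  stopifnot(all(c("dam", "sire") %in% names(crosses)))
  lo <- pmin(crosses$dam, crosses$sire)
  hi <- pmax(crosses$dam, crosses$sire)
  crosses$family <- paste(lo, hi, sep = "x")
  crosses
}

#' Build a two-generation pedigree from parents and crosses
#'
#' Founders (P1) are listed first with unknown dam and sire; each cross then
#' contributes `offspring_per_cross` F1 records carrying that cross's dam,
#' sire and family id.
#'
#' @param parents data frame with at least an `id` column (optionally
#'   `population`, `range`, `group`), or a vector of parent ids.
#' @param crosses data frame of crosses (see [build_partial_diallel()]),
#'   with families assigned if available.
#' @param offspring_per_cross non-negative integer.
#' @return a data frame of class `pedigree_qg` with columns `id`, `dam`,
#'   `sire` (`NA` = unknown), `generation` (`"P1"`/`"F1"`), `family`, plus
#'   any parent metadata merged onto founders.
#' @export
build_pedigree <- function(parents, crosses, offspring_per_cross = 2L) {
  if (is.atomic(parents)) parents <- data.frame(id = as.character(parents),
                                                stringsAsFactors = FALSE)
  stopifnot("id" %in% names(parents))
  offspring_per_cross <- as.integer(offspring_per_cross)
  if (offspring_per_cross < 0L) stop("offspring_per_cross must be >= 0")
  if (!"family" %in% names(crosses) && nrow(crosses) > 0)
    crosses <- assign_families(crosses)
  unknown <- setdiff(unique(c(crosses$dam, crosses$sire)), parents$id)
  if (length(unknown))
    stop("crosses reference unknown parents: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)

  founders <- data.frame(id = as.character(parents$id),
                         dam = NA_character_, sire = NA_character_,
                         generation = "P1", family = NA_character_,
                         stringsAsFactors = FALSE)
  extra <- setdiff(names(parents), "id")
  for (v in extra) founders[[v]] <- parents[[v]]

  if (offspring_per_cross > 0L && nrow(crosses) > 0) {
    k <- rep(seq_len(nrow(crosses)), each = offspring_per_cross)
    rep_no <- rep(seq_len(offspring_per_cross), times = nrow(crosses))
    f1 <- data.frame(id = paste0(crosses$dam[k], "x", crosses$sire[k], "_", rep_no),
                     dam = crosses$dam[k], sire = crosses$sire[k],
                     generation = "F1", family = crosses$family[k],
                     stringsAsFactors = FALSE)
    for (v in extra) f1[[v]] <- parents[[v]][match(f1$dam, parents$id)]
    ped <- rbind(founders, f1)
  } else {
    ped <- founders
  }
  rownames(ped) <- NULL
  class(ped) <- c("pedigree_qg", "data.frame")
  ped
}

# parents-before-offspring check; stops on cycles / missing parents
check_pedigree_order <- function(ped) {
  pos <- seq_len(nrow(ped))
  names(pos) <- ped$id
  if (anyDuplicated(ped$id)) stop("duplicate ids in pedigree", call. = FALSE)
  for (col in c("dam", "sire")) {
    p <- ped[[col]]
    known <- !is.na(p)
    if (any(known & !(p %in% ped$id)))
      stop("pedigree references missing ", col, " ids", call. = FALSE)
    bad <- known & pos[p] >= pos[ped$id]
    if (any(bad))
      stop("pedigree is not sorted parents-before-offspring (or contains a cycle)",
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Additive relationship matrix from a pedigree (tabular method)
#'
#' Computes the expected additive (numerator) relationship matrix A by the
#' recursive tabular method: founders are unrelated and non-inbred,
#' `A[i, j] = (A[j, dam(i)] + A[j, sire(i)]) / 2` for `j` preceding `i`, and
#' `A[i, i] = 1 + F_i` where `F_i` is half the relationship of `i`'s parents.
#'
#' @param pedigree a data frame with `id`, `dam`, `sire`, sorted so parents
#'   precede offspring (`NA` = unknown parent).
#' @return a symmetric numeric matrix with dimnames = pedigree ids.
#' @export
additive_relationship <- function(pedigree) {
  check_pedigree_order(pedigree)
  n <- nrow(pedigree)
  ids <- pedigree$id
  di <- match(pedigree$dam, ids)   # NA for founders
  si <- match(pedigree$sire, ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    d <- di[i]; s <- si[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (!is.na(d)) row <- row + A[j, d]
      if (!is.na(s)) row <- row + A[j, s]
      row <- row / 2
      A[j, i] <- row
      A[i, j] <- row
    }
    Fi <- if (!is.na(d) && !is.na(s)) 0.5 * A[d, s] else 0
    A[i, i] <- 1 + Fi
  }
  A
}

#' Sparse inverse of the additive relationship matrix
#'
#' Builds A-inverse directly from the pedigree with Henderson's rules. Valid
#' for non-inbred parents (exact here: founders are unrelated and there is a
#' single offspring generation, so no individual is inbred). Used by the
#' Gibbs sampler, where only A-inverse is needed.
#'
#' @param pedigree as in [additive_relationship()].
#' @return a sparse symmetric [Matrix::dsCMatrix-class] with dimnames.
#' @export
additive_relationship_inverse <- function(pedigree) {
  check_pedigree_order(pedigree)
  ids <- pedigree$id
  n <- length(ids)
  di <- match(pedigree$dam, ids)
  si <- match(pedigree$sire, ids)
  np <- (!is.na(di)) + (!is.na(si))
  alpha <- c(1, 4 / 3, 2)[np + 1L]  # 1 / (Mendelian variance share)
  k <- seq_len(n)
  ii <- k; jj <- k; xx <- alpha
  for (pcol in list(di, si)) {
    has <- !is.na(pcol)
    p <- pcol[has]; o <- k[has]; a <- alpha[has]
    ii <- c(ii, o, p, p); jj <- c(jj, p, o, p)
    xx <- c(xx, -a / 2, -a / 2, a / 4)
  }
  both <- !is.na(di) & !is.na(si)
  ii <- c(ii, di[both], si[both])
  jj <- c(jj, si[both], di[both])
  xx <- c(xx, rep(alpha[both] / 4, 2))
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                       dimnames = list(ids, ids), symmetric = FALSE,
                       repr = "C")
}

#' Validate a diallel crossing design
#'
#' Report-only check of a set of crosses against the canonical reciprocal
#' partial diallel: within each group every parent should appear `n - 1`
#' times as dam and `n - 1` times as sire, there should be no selfing, no
#' cross-group matings, and every cross should have its reciprocal.
#'
#' @param crosses data frame with `dam`, `sire` and optionally `group`.
#' @return a list of class `diallel_report` with elements `ok` (logical),
#'   `counts` (per-parent dam/sire counts and expectation), `selfings`,
#'   `cross_group`, and `missing_reciprocals`.
#' @export
validate_design <- function(crosses) {
  stopifnot(all(c("dam", "sire") %in% names(crosses)))
  if (!"group" %in% names(crosses)) crosses$group <- NA_character_
  selfings <- crosses[crosses$dam == crosses$sire, , drop = FALSE]

  # cross-group matings: a parent seen in >1 group, or dam/sire in
  # different groups for the same cross
  par_group <- unique(rbind(
    data.frame(id = crosses$dam, group = crosses$group, stringsAsFactors = FALSE),
    data.frame(id = crosses$sire, group = crosses$group, stringsAsFactors = FALSE)))
  multi <- names(which(tapply(par_group$group, par_group$id,
                              function(g) length(unique(g))) > 1))
  cross_group <- crosses[crosses$dam %in% multi | crosses$sire %in% multi, ,
                         drop = FALSE]

  key <- paste(crosses$dam, crosses$sire, sep = "\r")
  rkey <- paste(crosses$sire, crosses$dam, sep = "\r")
  nonself <- crosses$dam != crosses$sire
  missing_rec <- crosses[nonself & !(rkey %in% key), , drop = FALSE]

  counts <- lapply(split(crosses, crosses$group), function(cc) {
    ids <- unique(c(cc$dam, cc$sire))
    expected <- length(ids) - 1L
    data.frame(id = ids, group = cc$group[1],
               as_dam = as.integer(table(factor(cc$dam, ids))[ids]),
               as_sire = as.integer(table(factor(cc$sire, ids))[ids]),
               expected = expected, stringsAsFactors = FALSE)
  })
  counts <- do.call(rbind, counts)
  rownames(counts) <- NULL
  counts$ok <- counts$as_dam == counts$expected & counts$as_sire == counts$expected

  out <- list(ok = nrow(selfings) == 0 && nrow(cross_group) == 0 &&
                nrow(missing_rec) == 0 && all(counts$ok),
              counts = counts, selfings = selfings,
              cross_group = cross_group, missing_reciprocals = missing_rec)
  class(out) <- "diallel_report"
  out
}

#' @export
print.diallel_report <- function(x, ...) {
  cat("Diallel design report:", if (x$ok) "OK" else "violations found", "\n")
  cat("  parents with unbalanced dam/sire counts:", sum(!x$counts$ok), "\n")
  cat("  selfings:", nrow(x$selfings),
      " cross-group matings:", nrow(x$cross_group),
      " missing reciprocals:", nrow(x$missing_reciprocals), "\n")
  invisible(x)
}

#' Read / write pedigrees as 3-column text
#'
#' The on-disk dialect is the de facto standard consumed by animal-model
#' software: whitespace-separated columns `id sire dam`, one header line,
#' `"0"` for unknown parents.
#'
#' @param pedigree a pedigree data frame (`id`, `dam`, `sire`, ...).
#' @param file path.
#' @return `read_pedigree()` returns a `pedigree_qg` data frame with `id`,
#'   `dam`, `sire`; `write_pedigree()` returns `file` invisibly.
#' @export
write_pedigree <- function(pedigree, file) {
  out <- data.frame(id = pedigree$id,
                    sire = ifelse(is.na(pedigree$sire), "0", pedigree$sire),
                    dam = ifelse(is.na(pedigree$dam), "0", pedigree$dam))
  utils::write.table(out, file, quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_pedigree
#' @export
read_pedigree <- function(file) {
  raw <- utils::read.table(file, header = TRUE, colClasses = "character")
  names(raw) <- tolower(names(raw))
  stopifnot(all(c("id", "sire", "dam") %in% names(raw)))
  ped <- data.frame(id = raw$id,
                    dam = ifelse(raw$dam == "0", NA_character_, raw$dam),
                    sire = ifelse(raw$sire == "0", NA_character_, raw$sire),
                    stringsAsFactors = FALSE)
  class(ped) <- c("pedigree_qg", "data.frame")
  ped
}
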