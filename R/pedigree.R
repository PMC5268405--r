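#' Validate and topologically sort a pedigree
#'
#' Checks a raw pedigree table for structural soundness and returns a
#' `qg_pedigree` object sorted so that parents always precede their
#' offspring. The pedigree is the carrier of all relatedness information used
#' by the animal models: it defines the additive relationship matrix **A**.
#'
#' Validation enforces that (i) the parent map is acyclic, (ii) every named
#' sire or dam has its own record, (iii) sires are male and dams female, and
#' (iv) no parent is born after its offspring. Reproduction within the birth
#' year (parent cohort equal to offspring cohort) is allowed: in species such
#' as the snow vole a few females breed in the year they are born.
#'
#' @param raw A data.frame with columns `id`, `sire`, `dam`, `sex`
#'   (`"F"`/`"M"`), `cohort` (integer year). Unknown parents are `NA` or `""`.
#' @return A `qg_pedigree`: the sorted data.frame with attributes
#'   `n_maternities`, `n_paternities`, `depth` (per-individual generation
#'   number, founders = 1) and `index` (named integer map id -> row).
#' @examples
#' trio <- data.frame(id = c("s", "d", "o"), sire = c(NA, NA, "s"),
#'                    dam = c(NA, NA, "d"), sex = c("M", "F", "F"),
#'                    cohort = c(2000, 2000, 2001))
#' ped <- validate_pedigree(trio)
#' attr(ped, "n_maternities")
#' @export
validate_pedigree <- function(raw) {
  need <- c("id", "sire", "dam", "sex", "cohort")
  if (!all(need %in% names(raw))) {
    stop("pedigree table must have columns: ", paste(need, collapse = ", "))
  }
  ped <- data.frame(
    id     = as.character(raw$id),
    sire   = .na_parent(raw$sire),
    dam    = .na_parent(raw$dam),
    sex    = as.character(raw$sex),
    cohort = as.integer(raw$cohort),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(ped$id)) {
    stop("duplicated individual ids: ",
         paste(unique(ped$id[duplicated(ped$id)]), collapse = ", "))
  }
  if (!all(ped$sex %in% c("F", "M"))) {
    stop("sex must be 'F' or 'M'; offending ids: ",
         paste(ped$id[!ped$sex %in% c("F", "M")], collapse = ", "))
  }
  for (p in c("sire", "dam")) {
    miss <- setdiff(stats::na.omit(ped[[p]]), ped$id)
    if (length(miss)) {
      stop("named ", p, "(s) without an individual record: ",
           paste(miss, collapse = ", "))
    }
  }
  sex_of <- stats::setNames(ped$sex, ped$id)
  bad_sire <- ped$id[!is.na(ped$sire) & sex_of[ped$sire] != "M"]
  bad_dam  <- ped$id[!is.na(ped$dam) & sex_of[ped$dam] != "F"]
  if (length(bad_sire) || length(bad_dam)) {
    stop("sex-inconsistent parentage for offspring: ",
         paste(unique(c(bad_sire, bad_dam)), collapse = ", "))
  }
  coh_of <- stats::setNames(ped$cohort, ped$id)
  late_s <- !is.na(ped$sire) & coh_of[ped$sire] > ped$cohort
  late_d <- !is.na(ped$dam) & coh_of[ped$dam] > ped$cohort
  if (any(late_s | late_d)) {
    stop("parent born after offspring for: ",
         paste(ped$id[late_s | late_d], collapse = ", "))
  }

  ord <- .topo_sort(ped)
  ped <- ped[ord, , drop = FALSE]
  rownames(ped) <- NULL

  idx <- stats::setNames(seq_len(nrow(ped)), ped$id)
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  depth <- integer(nrow(ped))
  for (i in seq_len(nrow(ped))) {
    depth[i] <- 1L + max(0L, depth[si[i]], depth[di[i]])
  }
  structure(ped,
            class = c("qg_pedigree", "data.frame"),
            n_maternities = sum(!is.na(ped$dam)),
            n_paternities = sum(!is.na(ped$sire)),
            depth = depth,
            index = idx)
}

.na_parent <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & (x == "" | x == "NA" | x == "0")] <- NA_character_
  x
}

# Kahn topological sort, ties broken by (cohort, id) for determinism.
.topo_sort <- function(ped) {
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  indeg <- (si > 0L) + (di > 0L)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) if (p > 0L) children[[p]] <- c(children[[p]], i)
  }
  out <- integer(0)
  ready <- which(indeg == 0L)
  ready <- ready[order(ped$cohort[ready], ped$id[ready])]
  while (length(ready)) {
    i <- ready[1L]
    ready <- ready[-1L]
    out <- c(out, i)
    kids <- children[[i]]
    if (length(kids)) {
      indeg[kids] <- indeg[kids] - 1L
      new <- kids[indeg[kids] == 0L]
      if (length(new)) {
        ready <- c(ready, new)
        ready <- ready[order(ped$cohort[ready], ped$id[ready])]
      }
    }
  }
  if (length(out) < n) {
    on_cycle <- setdiff(seq_len(n), out)
    stop("pedigree contains a cycle involving individual '",
         ped$id[on_cycle[1L]], "'")
  }
  out
}

#' @export
print.qg_pedigree <- function(x, ...) {
  cat("qg_pedigree:", nrow(x), "individuals,",
      attr(x, "n_maternities"), "maternities,",
      attr(x, "n_paternities"), "paternities, max depth",
      max(attr(x, "depth")), "generations\n")
  invisible(x)
}

.ped_parent_idx <- function(ped) {
  stopifnot(inherits(ped, "qg_pedigree"))
  idx <- attr(ped, "index")
  list(
    si = ifelse(is.na(ped$sire), 0L, unname(idx[ped$sire])),
    di = ifelse(is.na(ped$dam), 0L, unname(idx[ped$dam]))
  )
}

#' Additive (numerator) relationship matrix
#'
#' Builds **A** by the tabular (recursive) method on a topologically sorted
#' pedigree: founders have \eqn{A_{ii} = 1}; for offspring o of s and d,
#' \eqn{A_{io} = (A_{is} + A_{id})/2} and \eqn{A_{oo} = 1 + A_{sd}/2}.
#' Unknown parents contribute zero, i.e. individuals with both parents
#' unknown are treated as unrelated base-population founders.
#'
#' @param ped A `qg_pedigree` from [validate_pedigree()].
#' @return A dense symmetric matrix with dimnames = individual ids. The
#'   diagonal equals `1 + F` where `F` is the inbreeding coefficient.
#' @export
additive_relationship <- function(ped) {
  stopifnot(inherits(ped, "qg_pedigree"))
  n <- nrow(ped)
  pp <- .ped_parent_idx(ped)
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- pp$si[i]; d <- pp$di[i]
    if (i > 1L) {
      prev <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (s > 0L) row <- row + 0.5 * A[s, prev]
      if (d > 0L) row <- row + 0.5 * A[d, prev]
      A[i, prev] <- row
      A[prev, i] <- row
    }
    A[i, i] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
  }
  A
}

#' Inbreeding coefficients from the pedigree
#'
#' @param ped A `qg_pedigree`.
#' @return Named numeric vector `F` (half the parents' relationship).
#' @export
inbreeding <- function(ped) {
  A <- additive_relationship(ped)
  stats::setNames(diag(A) - 1, ped$id)
}

#' Sparse inverse of the additive relationship matrix
#'
#' Direct construction of \eqn{A^{-1}} by Henderson's rules with the
#' Quaas correction for inbred parents, without forming or inverting the
#' dense matrix. Needed for mixed-model equations at pedigree scale.
#'
#' @param ped A `qg_pedigree`.
#' @param f Optional precomputed inbreeding coefficients in pedigree order;
#'   computed from the pedigree when `NULL`.
#' @return A `dgCMatrix` with dimnames = individual ids.
#' @export
a_inverse <- function(ped, f = NULL) {
  stopifnot(inherits(ped, "qg_pedigree"))
  n <- nrow(ped)
  pp <- .ped_parent_idx(ped)
  if (is.null(f)) f <- unname(inbreeding(ped))
  stopifnot(length(f) == n)
  # Mendelian sampling variance m_i, then alpha = 1/m_i
  trip_i <- integer(9L * n); trip_j <- integer(9L * n); trip_x <- numeric(9L * n)
  k <- 0L
  put <- function(i, j, v) {
    k <<- k + 1L
    trip_i[k] <<- i; trip_j[k] <<- j; trip_x[k] <<- v
  }
  for (i in seq_len(n)) {
    s <- pp$si[i]; d <- pp$di[i]
    m_i <- 1 -
      (if (s > 0L) 0.25 * (1 + f[s]) else 0) -
      (if (d > 0L) 0.25 * (1 + f[d]) else 0)
    a <- 1 / m_i
    put(i, i, a)
    for (p in c(s, d)) {
      if (p > 0L) {
        put(i, p, -a / 2); put(p, i, -a / 2)
        put(p, p, a / 4)
      }
    }
    if (s > 0L && d > 0L) {
      put(s, d, a / 4); put(d, s, a / 4)
    }
  }
  Ainv <- Matrix::sparseMatrix(i = trip_i[seq_len(k)], j = trip_j[seq_len(k)],
                               x = trip_x[seq_len(k)], dims = c(n, n),
                               dimnames = list(ped$id, ped$id))
  methods::as(Ainv, "generalMatrix")
}

#' Mean generation time from parent-offspring links
#'
#' The mean, over all parent-offspring links, of the parental age at the
#' birth of the offspring (offspring cohort minus parent cohort, in years).
#' Used to convert per-generation rates of evolution into per-year rates.
#'
#' @param ped A `qg_pedigree`.
#' @return Mean parental age in years (scalar).
#' @export
generation_time <- function(ped) {
  stopifnot(inherits(ped, "qg_pedigree"))
  coh <- stats::setNames(ped$cohort, ped$id)
  ages <- c(ped$cohort[!is.na(ped$sire)] - coh[ped$sire[!is.na(ped$sire)]],
            ped$cohort[!is.na(ped$dam)] - coh[ped$dam[!is.na(ped$dam)]])
  if (!length(ages)) stop("pedigree has no parent-offspring links")
  mean(ages)
}

#' Read a pedigree CSV
#'
#' Expects columns `id,sire,dam,sex,cohort`; unknown parents empty or `NA`.
#' @param path Path to the CSV file.
#' @return A validated `qg_pedigree`.
#' @export
read_pedigree <- function(path) {
  validate_pedigree(utils::read.csv(path, stringsAsFactors = FALSE,
                                    colClasses = "character"))
}

#' Write matrices in coordinate (sparse triplet) CSV form
#'
#' Writes `i,j,value` rows for the non-zero entries plus a JSON id-to-index
#' map alongside, so matrices can be reconstructed with their identifiers.
#' @param m A (possibly sparse) matrix with dimnames.
#' @param path Output CSV path; the index map goes to `<path>.index.json`.
#' @return `path`, invisibly.
#' @export
write_matrix_coo <- function(m, path) {
  tm <- methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE),
                                "generalMatrix"), "TsparseMatrix")
  df <- data.frame(i = tm@i + 1L, j = tm@j + 1L, value = tm@x)
  df <- df[order(df$i, df$j), ]
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(as.list(stats::setNames(seq_len(nrow(m)),
                                               rownames(m))),
                       paste0(path, ".index.json"), auto_unbox = TRUE)
  invisible(path)
}
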