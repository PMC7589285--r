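#' Validate and topologically order a pedigree
#'
#' Normalizes a 3-column pedigree (`id`, `dam`, `sire`) so that every named
#' parent has its own record (parents missing a record are inserted as
#' founders) and records are ordered with parents before offspring.  Unknown
#' parents are `NA`.  A cycle (an individual among its own ancestors) is an
#' error naming the individuals involved.
#'
#' @param ped Data frame with columns `id`, `dam`, `sire`.
#' @return The ordered pedigree data frame, with unknown parents as `NA`.
#' @export
as_pedigree <- function(ped) {
  need <- c("id", "dam", "sire")
  miss <- setdiff(need, names(ped))
  if (length(miss)) stop("pedigree lacks columns: ", paste(miss, collapse = ", "))
  id <- as.character(ped$id)
  dam <- .unknown_to_na(ped$dam)
  sire <- .unknown_to_na(ped$sire)
  if (anyDuplicated(id)) stop("duplicated individual id(s) in pedigree: ",
                              paste(unique(id[duplicated(id)]), collapse = ", "))
  parents <- setdiff(stats::na.omit(c(dam, sire)), id)
  if (length(parents)) {
    id <- c(id, parents)
    dam <- c(dam, rep(NA_character_, length(parents)))
    sire <- c(sire, rep(NA_character_, length(parents)))
  }
  n <- length(id)
  di <- match(dam, id)
  si <- match(sire, id)
  # Kahn's algorithm: peel individuals whose parents are already placed
  placed <- logical(n)
  parent_placed <- function(p) is.na(p) | placed[ifelse(is.na(p), 1L, p)]
  order_idx <- integer(0)
  repeat {
    ready <- !placed & parent_placed(di) & parent_placed(si)
    if (!any(ready)) break
    order_idx <- c(order_idx, which(ready))
    placed[ready] <- TRUE
  }
  if (!all(placed))
    stop("pedigree contains a cycle involving: ",
         paste(id[!placed], collapse = ", "))
  out <- data.frame(id = id[order_idx], dam = dam[order_idx],
                    sire = sire[order_idx], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# "", "NA", "0", "*" and NA all denote an unknown parent
.unknown_to_na <- function(x) {
  x <- trimws(as.character(x))
  x[x %in% c("", "NA", "0", "*") | is.na(x)] <- NA_character_
  x
}

#' Prune a pedigree to phenotyped individuals and their ancestors
#'
#' Returns the minimal pedigree containing every individual in
#' `phenotyped_ids` together with all of their ancestors, topologically
#' ordered.  Phenotyped ids missing from the pedigree are inserted as
#' founders with a warning (their relatedness to everyone else is then
#' unknown, i.e. zero).
#'
#' @param ped Pedigree data frame (`id`, `dam`, `sire`).
#' @param phenotyped_ids Character vector of ids with at least one phenotype.
#' @return Pruned, ordered pedigree data frame.
#' @export
prune_pedigree <- function(ped, phenotyped_ids) {
  ped <- as_pedigree(ped)
  phenotyped_ids <- unique(as.character(phenotyped_ids))
  extra <- setdiff(phenotyped_ids, ped$id)
  if (length(extra)) {
    warning(length(extra), " phenotyped id(s) absent from the pedigree; ",
            "inserted as founders")
    ped <- rbind(data.frame(id = extra, dam = NA_character_,
                            sire = NA_character_, stringsAsFactors = FALSE),
                 ped)
  }
  di <- match(ped$dam, ped$id)
  si <- match(ped$sire, ped$id)
  keep <- logical(nrow(ped))
  frontier <- match(phenotyped_ids, ped$id)
  while (length(frontier)) {
    keep[frontier] <- TRUE
    parents <- unique(stats::na.omit(c(di[frontier], si[frontier])))
    frontier <- parents[!keep[parents]]
  }
  as_pedigree(ped[keep, , drop = FALSE])
}

#' Additive genetic relationship matrix (tabular method)
#'
#' Builds the numerator relationship matrix `A` from a pedigree by the
#' tabular method: processing individuals parents-first,
#' `A[i, j] = 0.5 * (A[j, sire_i] + A[j, dam_i])` for previously processed
#' `j`, and `A[i, i] = 1 + 0.5 * A[sire_i, dam_i]` (so the diagonal is
#' `1 + F_i` with `F_i` the inbreeding coefficient).  Unknown parents are
#' treated as unrelated, non-inbred founders and contribute zero.
#'
#' @param ped Pedigree data frame; reordered with [as_pedigree()] if needed.
#' @return Dense symmetric matrix with ids as dimnames.
#' @export
additive_matrix <- function(ped) {
  ped <- as_pedigree(ped)
  n <- nrow(ped)
  di <- match(ped$dam, ped$id)
  si <- match(ped$sire, ped$id)
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      jj <- seq_len(i - 1L)
      v <- numeric(i - 1L)
      if (!is.na(s)) v <- v + A[jj, s]
      if (!is.na(d)) v <- v + A[jj, d]
      v <- 0.5 * v
      A[jj, i] <- v
      A[i, jj] <- v
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  A
}

#' Dominance genetic relationship matrix
#'
#' Builds the dominance relationship matrix `D` from a pedigree under the
#' standard non-inbred convention:
#' `D[i, j] = 0.25 * (A[s_i, s_j] * A[d_i, d_j] + A[s_i, d_j] * A[d_i, s_j])`
#' for `i != j`, zero whenever any of the four parents is unknown, and
#' `D[i, i] = 1`.
#'
#' @param ped Pedigree data frame.
#' @param A Additive relationship matrix on the same pedigree; computed with
#'   [additive_matrix()] if not supplied.
#' @return Dense symmetric matrix with unit diagonal and ids as dimnames.
#' @export
dominance_matrix <- function(ped, A = additive_matrix(ped)) {
  ped <- as_pedigree(ped)
  if (!identical(rownames(A), ped$id))
    A <- A[ped$id, ped$id, drop = FALSE]
  n <- nrow(ped)
  # augment A with a zero row/column standing in for unknown parents, so the
  # products vanish automatically whenever a parent is missing
  Aa <- rbind(cbind(A, 0), 0)
  u <- n + 1L
  si <- match(ped$sire, ped$id); si[is.na(si)] <- u
  di <- match(ped$dam, ped$id);  di[is.na(di)] <- u
  D <- 0.25 * (Aa[si, si, drop = FALSE] * Aa[di, di, drop = FALSE] +
                 Aa[si, di, drop = FALSE] * Aa[di, si, drop = FALSE])
  diag(D) <- 1
  dimnames(D) <- list(ped$id, ped$id)
  D
}

#' Mean female-male relatedness across breeding pairs
#'
#' Twice the mean pairwise kinship coefficient between pair members,
#' `2 * k_mean`, equal to the mean additive relationship `A[female, male]`
#' over the supplied pairs.  This scales the contribution of the cross-sex
#' additive genetic covariance to the phenotypic variance of the joint trait.
#'
#' @param A Additive relationship matrix with ids as dimnames.
#' @param pairs Data frame with columns `female_id` and `male_id`.
#' @return List with elements `k_mean` and `two_k_mean` (class
#'   `pair_relatedness`).
#' @export
mean_pair_relatedness <- function(A, pairs) {
  if (nrow(pairs) == 0L) stop("empty pair list")
  f <- as.character(pairs$female_id)
  m <- as.character(pairs$male_id)
  bad <- setdiff(c(f, m), rownames(A))
  if (length(bad)) stop("pair member(s) not indexed in A: ",
                        paste(unique(bad), collapse = ", "))
  two_k <- mean(A[cbind(f, m)])
  structure(list(k_mean = two_k / 2, two_k_mean = two_k),
            class = "pair_relatedness")
}

# Sparse precision (inverse) of a relationship matrix.  The nonzero graph of
# K is split into connected components, each block is inverted densely, and
# entries below `threshold` are dropped.  For the additive matrix over a full
# pedigree this recovers the classical sparse structure of A-inverse (one
# component, thresholded dense solve); for a dominance matrix restricted to
# phenotyped individuals the components are small sib/cousin clusters and the
# precision is genuinely block diagonal.
.sparse_precision <- function(K, label = "relationship matrix",
                              threshold = 1e-8) {
  K <- as.matrix(K)
  n <- nrow(K)
  adj <- K != 0
  comp <- integer(n)
  n_comp <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      n_comp <- n_comp + 1L
      frontier <- i
      while (length(frontier)) {
        comp[frontier] <- n_comp
        nb <- which(Matrix::rowSums(adj[, frontier, drop = FALSE]) > 0)
        frontier <- nb[comp[nb] == 0L]
      }
    }
  }
  ti <- vector("list", n_comp); tj <- ti; tx <- ti
  for (b in seq_len(n_comp)) {
    idx <- which(comp == b)
    Kb_inv <- .relationship_inverse(K[idx, idx, drop = FALSE], label)
    keep <- which(abs(Kb_inv) > threshold, arr.ind = TRUE)
    ti[[b]] <- idx[keep[, 1L]]
    tj[[b]] <- idx[keep[, 2L]]
    tx[[b]] <- Kb_inv[keep]
  }
  Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                       dims = c(n, n), dimnames = dimnames(K))
}

# inverse of a relationship matrix, with jitter escalation if the Cholesky
# fails at the 1e-10 pivot tolerance
.relationship_inverse <- function(K, label = "relationship matrix") {
  jitter <- 0
  for (attempt in 0:6) {
    Kj <- if (jitter > 0) K + diag(jitter, nrow(K)) else K
    ch <- tryCatch(chol(Kj), error = function(e) NULL)
    if (!is.null(ch) && min(diag(ch)) > 1e-10) {
      if (jitter > 0)
        message("added jitter ", jitter, " to the diagonal of the ", label)
      return(chol2inv(ch))
    }
    jitter <- if (jitter == 0) 1e-8 else jitter * 100
  }
  stop("could not factorize the ", label, " even with diagonal jitter")
}

#' Write a relationship matrix in MatrixMarket coordinate format
#'
#' @param K Dense or sparse symmetric matrix (e.g. from [additive_matrix()]).
#' @param file Output path; ids are written alongside as `<file>.ids`.
#' @return Invisibly, the file path.
#' @export
write_relationship_mm <- function(K, file) {
  M <- methods::as(methods::as(Matrix::Matrix(K, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  Matrix::writeMM(M, file)
  writeLines(rownames(K), paste0(file, ".ids"))
  invisible(file)
}
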