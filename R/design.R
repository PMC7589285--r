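#' Fixed-effect design matrix and random-effect incidence maps
#'
#' Builds the fixed design for the cue-response mixed models: an intercept,
#' treatment contrasts for the three-level female and male status factors
#' (yearling / older philopatric / older immigrant), the centered choice
#' date, and all two- and three-way interactions of the three variables
#' (18 columns in total), or an intercept-only variant.  Also returns sparse
#' incidence matrices mapping observations to the levels of the requested
#' grouping factors.
#'
#' @param data Data frame with columns `female_status`, `male_status`,
#'   `choice_date` (for the full design) and any grouping columns named in
#'   `random`.
#' @param fixed `"full"` (status x status x date factorial) or
#'   `"intercept"`.
#' @param random Character vector of grouping column names for which
#'   incidence matrices are wanted (may be empty).
#' @return List with `X` (dense design matrix) and `Z` (named list of sparse
#'   incidence matrices, one column per observed level).
#' @export
build_design <- function(data, fixed = c("full", "intercept"),
                         random = character(0)) {
  fixed <- match.arg(fixed)
  n <- nrow(data)
  if (fixed == "full") {
    status_levels <- c("yearling", "older_philopatric", "older_immigrant")
    for (col in c("female_status", "male_status")) {
      v <- as.character(data[[col]])
      bad <- setdiff(unique(v[!is.na(v)]), status_levels)
      if (length(bad))
        stop("unseen level(s) in '", col, "': ", paste(bad, collapse = ", "))
      if (anyNA(v)) stop("missing values in '", col, "'")
      data[[col]] <- factor(v, levels = status_levels)
    }
    if (!is.numeric(data$choice_date)) stop("'choice_date' must be numeric")
    date_c <- data$choice_date - mean(data$choice_date)
    X <- stats::model.matrix(
      ~ female_status * male_status * date_c,
      data = data.frame(female_status = data$female_status,
                        male_status = data$male_status, date_c = date_c))
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
      stop("fixed design is rank deficient; aliased columns: ",
           paste(aliased, collapse = ", "))
    }
  } else {
    X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  }
  Z <- lapply(random, function(col) {
    f <- factor(as.character(data[[col]]))
    if (anyNA(f)) stop("missing values in grouping column '", col, "'")
    .incidence(f)
  })
  names(Z) <- random
  list(X = X, Z = Z)
}

# sparse 0/1 incidence matrix of a factor (or of ids against a given index)
.incidence <- function(f, index = NULL) {
  if (is.null(index)) {
    f <- factor(f)
    index <- levels(f)
    j <- as.integer(f)
  } else {
    j <- match(as.character(f), index)
    if (anyNA(j)) stop("id(s) not covered by the matrix index: ",
                       paste(unique(as.character(f)[is.na(j)]), collapse = ", "))
  }
  Matrix::sparseMatrix(i = seq_along(j), j = j, x = 1,
                       dims = c(length(j), length(index)),
                       dimnames = list(NULL, index))
}
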