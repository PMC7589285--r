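#' Random-effect term constructors for the Gibbs sampler
#'
#' `term_iid()` defines an unstructured (iid) random effect over the levels
#' of a grouping vector, e.g. permanent individual, patch or nest-box
#' effects.  `term_struct()` defines a Gaussian effect with covariance
#' proportional to a known relationship matrix `K` (additive or dominance),
#' one effect per row of `K` actually used.  `term_genetic2()` defines the
#' joint female/male additive genetic effect with covariance
#' `C_A %x% A` over the union of female and male ids, estimating the
#' cross-sex additive genetic covariance.
#'
#' @param name Variance-component label; the sampled variance is reported as
#'   `V_<name>`.
#' @param group Vector (length = observations) of group labels.
#' @param ids Vector (length = observations) of individual ids mapped to
#'   rows of `K`.
#' @param K Relationship matrix with ids as dimnames; only rows needed by
#'   `ids` (plus, for `term_genetic2`, both sexes) are retained, which is an
#'   exact marginalization of the remaining individuals.
#' @param ids_f,ids_m Female and male ids per observation.
#' @return A term object for [gibbs_fit()].
#' @name gibbs_terms
NULL

#' @rdname gibbs_terms
#' @param block Location-update block this term belongs to: `"shared"`
#'   (drawn jointly with the fixed effects), `"f"` or `"m"`.  Female- and
#'   male-indexed effects are updated in separate blocks so that each
#'   block's mixed-model equations stay pedigree-sparse; the female-male
#'   coupling induced by shared observations enters through the
#'   conditioning, not the factorization.
#' @export
term_iid <- function(name, group, block = "shared") {
  Z <- .incidence(factor(as.character(group)))
  structure(list(kind = "iid", name = name, Z = Z, q = ncol(Z),
                 Kinv = NULL, labels = paste0("V_", name), block = block),
            class = "cueqg_term")
}

#' @rdname gibbs_terms
#' @param marginalize Restrict the effect vector to the ids observed in the
#'   data (exact marginalization through the submatrix of `K`; best for the
#'   nearly block-diagonal dominance matrix) or keep one effect per row of
#'   `K` (best for the additive matrix over a full pedigree, whose inverse
#'   is sparse).
#' @export
term_struct <- function(name, ids, K, marginalize = TRUE, block = "shared") {
  ids <- as.character(ids)
  miss <- setdiff(unique(ids), rownames(K))
  if (length(miss)) stop("id(s) missing from K for term '", name, "': ",
                         paste(utils::head(miss, 5L), collapse = ", "))
  use <- if (marginalize) intersect(rownames(K), unique(ids)) else rownames(K)
  Ksub <- if (marginalize) K[use, use, drop = FALSE] else K
  structure(list(kind = "struct", name = name,
                 Z = .incidence(ids, index = use), q = length(use),
                 Kinv = .sparse_precision(Ksub, paste0("K[", name, "]")),
                 labels = paste0("V_", name), block = block),
            class = "cueqg_term")
}

#' @rdname gibbs_terms
#' @export
term_genetic2 <- function(ids_f, ids_m, K, name = "A", marginalize = FALSE) {
  ids_f <- as.character(ids_f); ids_m <- as.character(ids_m)
  miss <- setdiff(unique(c(ids_f, ids_m)), rownames(K))
  if (length(miss)) stop("id(s) missing from K for the genetic term: ",
                         paste(utils::head(miss, 5L), collapse = ", "))
  use <- if (marginalize) intersect(rownames(K), unique(c(ids_f, ids_m)))
         else rownames(K)
  Ksub <- if (marginalize) K[use, use, drop = FALSE] else K
  structure(list(kind = "gen2", name = name,
                 Zf = .incidence(ids_f, index = use),
                 Zm = .incidence(ids_m, index = use),
                 qa = length(use),
                 Kinv = .sparse_precision(Ksub, "A (genetic term)"),
                 labels = c(paste0("V_", name, "_f"), paste0("V_", name, "_m"),
                            paste0("Cov_", name)),
                 block = c("f", "m")),
            class = "cueqg_term")
}

# upper-triangle triplets (i <= j) of a dense or sparse symmetric matrix
.upper_triplets <- function(K) {
  Kt <- methods::as(methods::as(Matrix::Matrix(K, sparse = TRUE),
                                "generalMatrix"), "TsparseMatrix")
  i <- Kt@i + 1L; j <- Kt@j + 1L; x <- Kt@x
  keep <- i <= j & x != 0
  list(i = i[keep], j = j[keep], x = x[keep])
}

# all triplets of a dense or sparse matrix
.all_triplets <- function(K) {
  Kt <- methods::as(methods::as(Matrix::Matrix(K, sparse = TRUE),
                                "generalMatrix"), "TsparseMatrix")
  keep <- Kt@x != 0
  list(i = Kt@i[keep] + 1L, j = Kt@j[keep] + 1L, x = Kt@x[keep])
}

# Precompute everything that does not change across iterations: the joint
# design, the cross-product pattern, and slot maps into the Cholesky input.
.gibbs_setup <- function(y, X, terms, priors) {
  n <- length(y)
  p <- ncol(X)
  Zblocks <- lapply(terms, function(tm)
    if (tm$kind == "gen2") cbind(tm$Zf, tm$Zm) else tm$Z)
  W <- Reduce(cbind, Zblocks, init = methods::as(Matrix::Matrix(X, sparse = TRUE),
                                                "CsparseMatrix"))
  d <- ncol(W)
  qs <- vapply(terms, function(tm) if (tm$kind == "gen2") 2L * tm$qa else tm$q, 0L)
  offs <- p + c(0L, cumsum(qs))[seq_along(terms)]  # 0-based offset per term

  M <- methods::as(Matrix::crossprod(W), "CsparseMatrix")  # dsC, upper
  Mi <- M@i + 1L
  Mj <- rep.int(seq_len(d), diff(M@p))
  Mx <- M@x
  Wty <- as.numeric(Matrix::crossprod(W, y))

  # prior-precision triplets: (i, j, base value, multiplier group)
  gi <- seq_len(p); gj <- seq_len(p)
  gx <- rep(1e-8, p); ggrp <- rep(1L, p)           # group 1: fixed ridge
  grp_of_term <- vector("list", length(terms))
  next_grp <- 2L
  for (k in seq_along(terms)) {
    tm <- terms[[k]]
    o <- offs[k]
    if (tm$kind == "iid") {
      gi <- c(gi, o + seq_len(tm$q)); gj <- c(gj, o + seq_len(tm$q))
      gx <- c(gx, rep(1, tm$q)); ggrp <- c(ggrp, rep(next_grp, tm$q))
      grp_of_term[[k]] <- next_grp; next_grp <- next_grp + 1L
    } else if (tm$kind == "struct") {
      tr <- .upper_triplets(tm$Kinv)
      gi <- c(gi, o + tr$i); gj <- c(gj, o + tr$j)
      gx <- c(gx, tr$x); ggrp <- c(ggrp, rep(next_grp, length(tr$x)))
      grp_of_term[[k]] <- next_grp; next_grp <- next_grp + 1L
    } else {                                        # gen2: ff, fm, mm blocks
      up <- .upper_triplets(tm$Kinv)
      al <- .all_triplets(tm$Kinv)
      qa <- tm$qa
      gi <- c(gi, o + up$i, o + al$i, o + qa + up$i)
      gj <- c(gj, o + up$j, o + qa + al$j, o + qa + up$j)
      gx <- c(gx, up$x, al$x, up$x)
      ggrp <- c(ggrp, rep(next_grp, length(up$x)),
                rep(next_grp + 1L, length(al$x)),
                rep(next_grp + 2L, length(up$x)))
      grp_of_term[[k]] <- next_grp:(next_grp + 2L)
      next_grp <- next_grp + 3L
    }
  }

  C0 <- Matrix::sparseMatrix(i = c(Mi, gi), j = c(Mj, gj),
                             x = c(Mx, gx), dims = c(d, d), symmetric = TRUE)
  Ci <- C0@i + 1L
  Cj <- rep.int(seq_len(d), diff(C0@p))
  keyC <- (Cj - 1) * d + Ci
  mapM <- match((Mj - 1) * d + Mi, keyC)
  mapG <- match((gj - 1) * d + gi, keyC)
  if (anyNA(mapM) || anyNA(mapG)) stop("internal error: pattern map failed")

  # location-update blocks: fixed effects and "shared" terms together,
  # female-indexed and male-indexed effects separately (keeps each block's
  # equations pedigree-sparse; see term constructors)
  blk_of_col <- rep("shared", d)
  for (k in seq_along(terms)) {
    tm <- terms[[k]]
    o <- offs[k]
    if (tm$kind == "gen2") {
      blk_of_col[o + seq_len(tm$qa)] <- tm$block[1L]
      blk_of_col[o + tm$qa + seq_len(tm$qa)] <- tm$block[2L]
    } else blk_of_col[o + seq_len(qs[k])] <- tm$block %||% "shared"
  }
  loc_blocks <- lapply(unique(blk_of_col), function(b) {
    cols <- which(blk_of_col == b)
    loc <- integer(d)
    loc[cols] <- seq_along(cols)
    sel <- which(blk_of_col[Ci] == b & blk_of_col[Cj] == b)
    li <- loc[Ci[sel]]
    lj <- loc[Cj[sel]]
    ord <- order(lj, li)
    Cbb0 <- Matrix::sparseMatrix(i = li[ord], j = lj[ord],
                                 x = rep(1, length(ord)),
                                 dims = c(length(cols), length(cols)),
                                 symmetric = TRUE)
    stopifnot(length(Cbb0@x) == length(ord))
    list(name = b, cols = cols, Cbb0 = Cbb0, slot_map = sel[ord])
  })

  # column -> scale slot (0 = fixed effects, unscaled)
  col_slot <- integer(d)
  slot_of_term <- vector("list", length(terms))
  next_slot <- 1L
  for (k in seq_along(terms)) {
    tm <- terms[[k]]
    o <- offs[k]
    if (tm$kind == "gen2") {
      col_slot[o + seq_len(tm$qa)] <- next_slot
      col_slot[o + tm$qa + seq_len(tm$qa)] <- next_slot + 1L
      slot_of_term[[k]] <- c(next_slot, next_slot + 1L)
      next_slot <- next_slot + 2L
    } else {
      col_slot[o + seq_len(qs[k])] <- next_slot
      slot_of_term[[k]] <- next_slot
      next_slot <- next_slot + 1L
    }
  }

  list(n = n, p = p, d = d, W = W, X = X, Mi = Mi, Mj = Mj, Mx = Mx,
       Wty = Wty, C0 = C0, nnzC = length(C0@x), mapM = mapM, mapG = mapG,
       gx = gx, ggrp = ggrp, n_grp = next_grp - 1L,
       grp_of_term = grp_of_term, col_slot = col_slot,
       slot_of_term = slot_of_term, n_slot = next_slot - 1L,
       offs = offs, qs = qs, loc_blocks = loc_blocks)
}

# one chain of the blocked Gibbs sampler; returns a matrix of retained draws
.gibbs_chain <- function(y, setup, terms, priors, n_iter, burn_in, thin,
                         seed) {
  set.seed(seed)
  n <- setup$n; p <- setup$p; d <- setup$d
  nu_r <- priors$residual$nu; V_r <- priors$residual$V
  nu_v <- priors$variance$nu; V_v <- priors$variance$V
  aV <- priors$variance$alpha_V; amu <- priors$variance$alpha_mu
  nu_g <- priors$genetic2$nu; V_g <- priors$genetic2$V
  aV_g <- priors$genetic2$alpha_V

  sigma2_e <- stats::var(y) %||% 1
  if (!is.finite(sigma2_e) || sigma2_e <= 0) sigma2_e <- 1
  alpha <- rep(1, setup$n_slot)           # working parameters, one per slot
  sig2_eta <- rep(sigma2_e / 2, length(terms))  # scalar-term base variances
  Psi <- lapply(terms, function(tm)
    if (tm$kind == "gen2") diag(2) * sigma2_e / 2 else NULL)

  K <- length(terms)
  labels <- c(colnames(setup$X), unlist(lapply(terms, `[[`, "labels")), "V_R")
  n_keep <- floor((n_iter - burn_in) / thin)
  out <- matrix(NA_real_, n_keep, length(labels),
                dimnames = list(NULL, labels))
  keep_at <- burn_in + thin * seq_len(n_keep)

  gmult <- numeric(setup$n_grp)
  gmult[1L] <- 1                          # ridge group
  Chb <- vector("list", length(setup$loc_blocks))
  theta <- numeric(d)
  kept <- 0L
  for (it in seq_len(n_iter)) {
    # --- multipliers of the prior-precision triplets
    for (k in seq_len(K)) {
      tm <- terms[[k]]
      g <- setup$grp_of_term[[k]]
      if (tm$kind == "gen2") {
        Pinv <- solve(Psi[[k]])
        gmult[g] <- c(Pinv[1, 1], Pinv[1, 2], Pinv[2, 2])
      } else gmult[g] <- 1 / sig2_eta[k]
    }
    # --- scale vector from working parameters
    s <- c(rep(1, p), numeric(d - p))
    if (setup$n_slot > 0L) {
      nz <- setup$col_slot > 0L
      s[nz] <- alpha[setup$col_slot[nz]]
    }
    # --- assemble the mixed-model-equation matrix
    xC <- numeric(setup$nnzC)
    xC[setup$mapM] <- setup$Mx * s[setup$Mi] * s[setup$Mj] / sigma2_e
    xC[setup$mapG] <- xC[setup$mapG] + setup$gx * gmult[setup$ggrp]
    C <- setup$C0
    C@x <- xC
    # --- block-wise draw of the location effects from their joint full
    #     conditionals (one sparse Cholesky solve per block)
    b_full <- s * setup$Wty / sigma2_e
    for (bi in seq_along(setup$loc_blocks)) {
      bk <- setup$loc_blocks[[bi]]
      Cbb <- bk$Cbb0
      Cbb@x <- xC[bk$slot_map]
      Chb[[bi]] <- if (is.null(Chb[[bi]]))
        Matrix::Cholesky(Cbb, LDL = FALSE, super = TRUE)
      else Matrix::update(Chb[[bi]], Cbb)
      w <- as.numeric(C %*% theta)
      rhs <- b_full[bk$cols] - w[bk$cols] +
        as.numeric(Cbb %*% theta[bk$cols])
      mu <- as.numeric(Matrix::solve(Chb[[bi]], rhs, system = "A"))
      v <- Matrix::solve(Chb[[bi]], stats::rnorm(length(bk$cols)),
                         system = "Lt")
      theta[bk$cols] <- mu + as.numeric(Matrix::solve(Chb[[bi]], v,
                                                      system = "Pt"))
    }
    beta <- theta[seq_len(p)]

    eta <- vector("list", K)
    gfit <- vector("list", K)
    r <- y - as.numeric(setup$X %*% beta)
    for (k in seq_len(K)) {
      tm <- terms[[k]]
      o <- setup$offs[k]
      if (tm$kind == "gen2") {
        ef <- theta[o + seq_len(tm$qa)]
        em <- theta[o + tm$qa + seq_len(tm$qa)]
        eta[[k]] <- list(f = ef, m = em)
        gfit[[k]] <- list(f = as.numeric(tm$Zf %*% ef),
                          m = as.numeric(tm$Zm %*% em))
        sl <- setup$slot_of_term[[k]]
        r <- r - alpha[sl[1L]] * gfit[[k]]$f - alpha[sl[2L]] * gfit[[k]]$m
      } else {
        eta[[k]] <- theta[o + seq_len(tm$q)]
        gfit[[k]] <- as.numeric(tm$Z %*% eta[[k]])
        r <- r - alpha[setup$slot_of_term[[k]]] * gfit[[k]]
      }
    }
    # --- working-parameter (parameter expansion) draws
    for (k in seq_len(K)) {
      tm <- terms[[k]]
      if (tm$kind == "gen2") {
        sl <- setup$slot_of_term[[k]]
        Xa <- cbind(gfit[[k]]$f, gfit[[k]]$m)
        r2 <- r + Xa %*% alpha[sl]
        Prec <- crossprod(Xa) / sigma2_e + diag(1 / aV_g, 2)
        Rp <- chol(Prec)
        mean_a <- backsolve(Rp, forwardsolve(t(Rp), crossprod(Xa, r2) / sigma2_e))
        a_new <- as.numeric(mean_a + backsolve(Rp, stats::rnorm(2)))
        alpha[sl] <- a_new
        r <- as.numeric(r2 - Xa %*% a_new)
      } else {
        sl <- setup$slot_of_term[[k]]
        g <- gfit[[k]]
        r1 <- r + alpha[sl] * g
        prec <- sum(g * g) / sigma2_e + 1 / aV
        mean_a <- (sum(g * r1) / sigma2_e + amu / aV) / prec
        a_new <- stats::rnorm(1, mean_a, sqrt(1 / prec))
        alpha[sl] <- a_new
        r <- r1 - a_new * g
      }
    }
    # --- residual variance
    sigma2_e <- 1 / stats::rgamma(1, (nu_r + n) / 2,
                                  rate = (nu_r * V_r + sum(r * r)) / 2)
    # --- base variances / working covariance of the genetic block
    for (k in seq_len(K)) {
      tm <- terms[[k]]
      if (tm$kind == "gen2") {
        uf <- tm$Kinv %*% eta[[k]]$f
        um <- tm$Kinv %*% eta[[k]]$m
        S <- matrix(c(sum(eta[[k]]$f * uf), sum(eta[[k]]$m * uf),
                      sum(eta[[k]]$f * um), sum(eta[[k]]$m * um)), 2, 2)
        S <- (S + t(S)) / 2
        df <- nu_g + tm$qa
        scale <- nu_g * V_g + S
        Wdraw <- stats::rWishart(1, df, solve(scale))[, , 1L]
        Psi[[k]] <- solve(Wdraw)
      } else {
        quad <- if (tm$kind == "iid") sum(eta[[k]]^2)
                else as.numeric(eta[[k]] %*% (tm$Kinv %*% eta[[k]]))
        sig2_eta[k] <- 1 / stats::rgamma(1, (nu_v + tm$q) / 2,
                                         rate = (nu_v * V_v + quad) / 2)
      }
    }
    # --- record
    if (kept < n_keep && it == keep_at[kept + 1L]) {
      kept <- kept + 1L
      vals <- beta
      for (k in seq_len(K)) {
        tm <- terms[[k]]
        if (tm$kind == "gen2") {
          sl <- setup$slot_of_term[[k]]
          Dm <- diag(alpha[sl], 2)
          CA <- Dm %*% Psi[[k]] %*% Dm
          vals <- c(vals, CA[1, 1], CA[2, 2], CA[1, 2])
        } else {
          vals <- c(vals, alpha[setup$slot_of_term[[k]]]^2 * sig2_eta[k])
        }
      }
      out[kept, ] <- c(vals, sigma2_e)
    }
  }
  out
}

#' Fit a Gaussian mixed model by blocked Gibbs sampling
#'
#' Samples from the posterior of a Gaussian mixed model with the given fixed
#' design and random-effect terms.  Each iteration (i) draws the location
#' effects (fixed and random) from their multivariate-normal full
#' conditionals by sparse Cholesky solves of the mixed-model equations --
#' jointly when all terms share one update block, otherwise block by block
#' (fixed plus shared terms, female-indexed terms, male-indexed terms),
#' which keeps each factorization pedigree-sparse --
#' (ii) draws each working (parameter-expansion) scalar from its Gaussian
#' full conditional, and (iii) draws the variance components from their
#' scaled inverse-chi-squared / inverse-Wishart full conditionals.  Reported
#' variance components are the products of the working parameters and base
#' variances, matching the parameter-expanded prior.
#'
#' @param y Numeric response vector without missing values.
#' @param X Fixed-effect design matrix (see [build_design()]).
#' @param terms List of random-effect terms from [term_iid()],
#'   [term_struct()], [term_genetic2()] (may be empty).
#' @param priors A [default_priors()] object.
#' @param settings An [mcmc_settings()] object.
#' @return Object of class `cueqg_samples`: list with `draws` (matrix of
#'   retained draws, fixed effects then variance components then `V_R`),
#'   `chain` (chain label per row), `settings`, and `diagnostics` (per
#'   parameter: PSRF across chains, summed ESS, mean lag-1 autocorrelation).
#' @export
gibbs_fit <- function(y, X, terms = list(), priors = default_priors(),
                      settings = mcmc_settings()) {
  if (anyNA(y) || any(!is.finite(y)))
    stop("response contains missing or non-finite values; drop them upstream")
  if (length(terms) && !all(vapply(terms, inherits, TRUE, "cueqg_term")))
    stop("'terms' must be built with term_iid()/term_struct()/term_genetic2()")
  setup <- .gibbs_setup(y, X, terms, priors)
  chains <- lapply(seq_len(settings$n_chains), function(ch)
    .gibbs_chain(y, setup, terms, priors, settings$n_iter,
                 settings$burn_in, settings$thin,
                 seed = settings$chain_seeds[ch]))
  draws <- do.call(rbind, chains)
  chain <- rep(seq_along(chains), vapply(chains, nrow, 0L))
  if (any(draws[, ncol(draws)] <= 0)) stop("non-positive residual draw")
  diagnostics <- .sample_diagnostics(chains, colnames(draws))
  structure(list(draws = draws, chain = chain, settings = settings,
                 priors = priors, n_obs = setup$n,
                 term_labels = unlist(lapply(terms, `[[`, "labels")),
                 diagnostics = diagnostics),
            class = "cueqg_samples")
}

.sample_diagnostics <- function(chains, params) {
  do.call(rbind, lapply(params, function(pm) {
    series <- lapply(chains, function(m) m[, pm])
    ess <- vapply(series, function(x) as.numeric(effective_sample_size(x)), 0)
    lag1 <- vapply(series, function(x)
      attr(effective_sample_size(x), "lag1") %||% NA_real_, 0)
    data.frame(parameter = pm,
               psrf = if (length(series) >= 2L) gelman_rubin(series) else NA_real_,
               ess = sum(ess), lag1 = mean(lag1, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
}
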