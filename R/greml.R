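#' REML fitting options
#'
#' @param max_iter maximum optimizer iterations
#' @param tol convergence threshold on the change in restricted log-likelihood
#' @param floor_fraction lower bound for each variance component, as a
#'   fraction of the phenotypic variance (mirrors the usual GREML constraint)
#' @param em_warmup_iters number of EM iterations before switching to
#'   average-information updates
#' @return list of class `reml_options`
#' @export
reml_options <- function(max_iter = 100L, tol = 1e-8,
                         floor_fraction = 1e-6, em_warmup_iters = 3L) {
  stopifnot(floor_fraction > 0, tol > 0, max_iter >= 1)
  structure(list(max_iter = as.integer(max_iter), tol = tol,
                 floor_fraction = floor_fraction,
                 em_warmup_iters = as.integer(em_warmup_iters)),
            class = "reml_options")
}

#' Restricted log-likelihood of the one-component mixed model
#'
#' For the model `y = X b + g + e` with `Var(g) = sigma_g2 * A` and
#' `Var(e) = sigma_e2 * I`, returns the REML log-likelihood
#' `-0.5 * (log|V| + log|X' V^-1 X| + y' P y)` where
#' `V = sigma_g2 A + sigma_e2 I` and
#' `P = V^-1 - V^-1 X (X' V^-1 X)^-1 X' V^-1`.
#'
#' The additive constant `-(n - c)/2 * log(2*pi)` is omitted; the convention
#' is applied identically to full and null models so likelihood-ratio
#' statistics are convention-free.  This dense implementation is the reference
#' path; [fit_reml()] uses an equivalent eigendecomposition path.
#'
#' @param y phenotype vector
#' @param x covariate matrix (full column rank, includes intercept)
#' @param a a `grm` or symmetric matrix
#' @param sigma_g2,sigma_e2 variance components (`V` must be positive definite)
#' @return restricted log-likelihood (scalar)
#' @export
restricted_loglik <- function(y, x, a, sigma_g2, sigma_e2) {
  av <- as_grm_matrix(a)
  n <- length(y)
  v <- sigma_g2 * av + diag(sigma_e2, n)
  cv <- tryCatch(chol(v), error = function(e)
    stop_herimap("V = sigma_g2*A + sigma_e2*I is not positive definite",
                 "herimap_value_error"))
  logdet_v <- 2 * sum(log(diag(cv)))
  vi_x <- backsolve(cv, forwardsolve(t(cv), x))
  vi_y <- backsolve(cv, forwardsolve(t(cv), y))
  xtvix <- crossprod(x, vi_x)
  cb <- tryCatch(chol(xtvix), error = function(e)
    stop_herimap("X' V^-1 X is singular", "herimap_value_error"))
  logdet_b <- 2 * sum(log(diag(cb)))
  b <- crossprod(x, vi_y)
  beta <- backsolve(cb, forwardsolve(t(cb), b))
  ypy <- sum(y * vi_y) - sum(b * beta)
  -0.5 * (logdet_v + logdet_b + ypy)
}

# Precompute the rotated quantities shared by every trait fitted against the
# same GRM and covariates: eigendecomposition of A (eigenvalues clipped at 0
# against numerical noise) and the rotated design U'X.
reml_prep <- function(a, x) {
  av <- as_grm_matrix(a)
  es <- eigen(av, symmetric = TRUE)
  lambda <- pmax(es$values, 0)
  xt <- crossprod(es$vectors, x)
  qrx <- qr(xt)
  if (qrx$rank < ncol(xt)) {
    stop_herimap("covariate matrix is rank deficient", "herimap_value_error")
  }
  logdet_xx <- sum(log(abs(diag(qr.R(qrx)))^2))
  list(u = es$vectors, lambda = lambda, xt = xt, qrx = qrx,
       logdet_xx = logdet_xx, n = nrow(av), c = ncol(x))
}

# loglik + working quantities at (sg, se), all in the eigenbasis of A
reml_state <- function(yt, xt, lambda, sg, se) {
  d <- sg * lambda + se
  xd <- xt / d
  bmat <- crossprod(xt, xd)
  cb <- chol(bmat)
  bvec <- crossprod(xd, yt)
  beta <- backsolve(cb, forwardsolve(t(cb), bvec))
  r <- yt - drop(xt %*% beta)
  s <- r / d                       # rotated P y
  ypy <- sum(yt * s)
  ll <- -0.5 * (sum(log(d)) + 2 * sum(log(diag(cb))) + ypy)
  list(d = d, xd = xd, cb = cb, s = s, ll = ll)
}

# apply rotated P to a rotated vector
reml_apply_p <- function(st, xt, v) {
  v / st$d - drop(st$xd %*% backsolve(st$cb, forwardsolve(t(st$cb),
                                                          crossprod(st$xd, v))))
}

reml_trace_pw <- function(st, xt, w) {
  binv <- chol2inv(st$cb)
  m <- crossprod(st$xd * w, st$xd)
  sum(w / st$d) - sum(binv * m)
}

#' Fit the one-component GREML model by AI-REML
#'
#' Maximizes the restricted likelihood of `y = X b + g + e`,
#' `Var(g) = sigma_g2 * A`, `Var(e) = sigma_e2 * I`, subject to each component
#' staying above `floor_fraction * var(y)`.  Optimization runs a few EM
#' warm-up iterations followed by average-information updates with
#' step-halving whenever a step would decrease the likelihood.  Heritability
#' is `h2 = sigma_g2 / (sigma_g2 + sigma_e2)`; its standard error comes from
#' the delta method on the inverse AI matrix (flagged unreliable when a
#' component is constrained).  The null model (`sigma_g2 = 0`) has the closed
#' form `sigma_e2 = RSS / (n - c)`; the likelihood-ratio statistic is referred
#' to the boundary mixture `0.5*chi2_0 + 0.5*chi2_1`, so
#' `p = 0.5 * P(chi2_1 >= LRT)` and exactly 0.5 when the genetic component
#' sits on its floor (an LRT below the convergence tolerance is reported as 0).
#'
#' @param y phenotype vector (finite, non-constant)
#' @param x covariate matrix from [build_covariates()]
#' @param a a `grm` (or a precomputed preparation from an internal call)
#' @param opts a [reml_options()]
#' @return object of class `herit_fit`; see [tidy.herit_fit()]
#' @export
fit_reml <- function(y, x, a, opts = reml_options()) {
  prep <- if (is.list(a) && !is.null(a$lambda)) a else reml_prep(a, x)
  yt <- drop(crossprod(prep$u, y))
  fit_reml_rotated(yt, prep, var(y), opts)
}

fit_reml_rotated <- function(yt, prep, vary, opts) {
  n <- prep$n; cc <- prep$c
  if (!all(is.finite(yt))) {
    stop_herimap("phenotype contains non-finite values", "herimap_value_error")
  }
  if (vary <= 0) {
    stop_herimap("phenotype is constant", "herimap_value_error")
  }
  if (n < cc + 2) {
    stop_herimap("need N >= C + 2 for REML", "herimap_value_error")
  }
  xt <- prep$xt; lambda <- prep$lambda
  floor_v <- opts$floor_fraction * vary

  # null model: V = sigma_e2 * I, closed form
  r0 <- qr.resid(prep$qrx, yt)
  rss <- sum(r0^2)
  sig0 <- rss / (n - cc)
  ll_null <- -0.5 * ((n - cc) * log(sig0) + prep$logdet_xx + (n - cc))

  sg <- se <- vary / 2
  st <- reml_state(yt, xt, lambda, sg, se)
  converged <- FALSE
  n_iter <- 0L
  ai <- NULL

  # step-halve a proposal toward the current point; NULL if no fraction of
  # the step improves the likelihood (never accept a downhill move)
  try_step <- function(prop, sg, se, st) {
    frac <- 1
    repeat {
      cand <- pmax(c(sg, se) + frac * (prop - c(sg, se)), floor_v)
      st_new <- reml_state(yt, xt, lambda, cand[1], cand[2])
      if (st_new$ll >= st$ll - 1e-12) {
        return(list(cand = cand, st = st_new))
      }
      frac <- frac / 2
      if (frac < 1e-4) return(NULL)
    }
  }

  for (it in seq_len(opts$max_iter)) {
    n_iter <- it
    s <- st$s
    q1 <- lambda * s
    tr_pl <- reml_trace_pw(st, xt, lambda)
    tr_p <- reml_trace_pw(st, xt, rep(1, n))
    sc_g <- -0.5 * (tr_pl - sum(s * q1))
    sc_e <- -0.5 * (tr_p - sum(s * s))
    prop_em <- c(sg + sg^2 * 2 * sc_g / n, se + se^2 * 2 * sc_e / n)

    if (it <= opts$em_warmup_iters) {
      res <- try_step(prop_em, sg, se, st)
    } else {
      pq1 <- reml_apply_p(st, xt, q1)
      ps <- reml_apply_p(st, xt, s)
      ai <- matrix(c(sum(q1 * pq1), sum(q1 * ps),
                     sum(q1 * ps), sum(s * ps)), 2, 2) / 2
      step <- tryCatch(solve(ai, c(sc_g, sc_e)), error = function(e) NULL)
      res <- if (!is.null(step) && all(is.finite(step))) {
        try_step(c(sg, se) + step, sg, se, st)
      } else {
        NULL
      }
      if (is.null(res)) res <- try_step(prop_em, sg, se, st)
    }
    if (is.null(res)) {          # no uphill move left: at a (boundary) optimum
      converged <- TRUE
      break
    }
    delta <- res$st$ll - st$ll
    sg <- res$cand[1]; se <- res$cand[2]; st <- res$st
    if (it > opts$em_warmup_iters && abs(delta) < opts$tol) {
      converged <- TRUE
      break
    }
  }

  at_floor_g <- sg <= floor_v * (1 + 1e-8)
  at_floor_e <- se <= floor_v * (1 + 1e-8)
  constrained <- at_floor_g || at_floor_e

  h2 <- sg / (sg + se)
  h2_se <- NA_real_
  if (is.null(ai)) {           # converged during warm-up window; compute AI here
    s <- st$s; q1 <- lambda * s
    pq1 <- reml_apply_p(st, xt, q1)
    ps <- reml_apply_p(st, xt, s)
    ai <- matrix(c(sum(q1 * pq1), sum(q1 * ps),
                   sum(q1 * ps), sum(s * ps)), 2, 2) / 2
  }
  vc <- tryCatch(solve(ai), error = function(e) NULL)
  if (!is.null(vc)) {
    gr <- c(se, -sg) / (sg + se)^2
    vh <- drop(crossprod(gr, vc %*% gr))
    if (is.finite(vh) && vh >= 0) h2_se <- sqrt(vh)
  }

  lrt <- max(0, 2 * (st$ll - ll_null))
  if (lrt < opts$tol) lrt <- 0           # below convergence resolution
  p <- 0.5 * pchisq(lrt, df = 1, lower.tail = FALSE)
  p <- min(max(p, 1e-300), 1)

  structure(list(
    sigma_g2 = sg, sigma_e2 = se, h2 = h2, h2_se = h2_se,
    loglik_full = st$ll, loglik_null = ll_null, lrt = lrt, p_value = p,
    n_iter = n_iter, converged = converged, constrained = constrained,
    n = n, n_covariates = cc), class = "herit_fit")
}

#' @export
print.herit_fit <- function(x, ...) {
  cat(sprintf(
    "<herit_fit> h2 = %.4f (SE %.4f), sigma_g2 = %.4g, sigma_e2 = %.4g\n",
    x$h2, x$h2_se, x$sigma_g2, x$sigma_e2))
  cat(sprintf("  LRT = %.4g, p = %.4g, %d iter, converged: %s%s\n",
              x$lrt, x$p_value, x$n_iter, x$converged,
              if (x$constrained) " (component at floor)" else ""))
  invisible(x)
}

#' Tidy a fitted heritability model
#' @param x a `herit_fit`
#' @param ... unused
#' @return one-row tibble of estimates
#' @export
tidy.herit_fit <- function(x, ...) {
  tibble(sigma_g2 = x$sigma_g2, sigma_e2 = x$sigma_e2,
         h2 = x$h2, h2_se = x$h2_se, lrt = x$lrt, p_value = x$p_value,
         constrained = x$constrained)
}

#' One-row fit summary of a heritability model
#' @param x a `herit_fit`
#' @param ... unused
#' @export
glance.herit_fit <- function(x, ...) {
  tibble(loglik_full = x$loglik_full, loglik_null = x$loglik_null,
         n_iter = x$n_iter, converged = x$converged, nobs = x$n)
}

#' Fit GREML to every column of a trait matrix
#'
#' Shares one eigendecomposition of the GRM across all traits (voxels or
#' regions), which is what makes voxelwise mapping tractable; results are
#' identical to calling [fit_reml()] per column.  Degenerate columns
#' (constant or non-finite) are recorded with `status != "ok"` and the batch
#' continues.
#'
#' @param pheno `N x V` matrix (a `voxel_qt`'s `values`, a region QT matrix,
#'   or any matrix with sample rownames)
#' @param x covariate matrix
#' @param a a `grm`
#' @param opts a [reml_options()]
#' @return tibble with one row per trait: `trait`, variance components, `h2`,
#'   `h2_se`, log-likelihoods, `lrt`, `p_value`, `n_iter`, `converged`,
#'   `constrained`, `status`
#' @export
fit_reml_batch <- function(pheno, x, a, opts = reml_options()) {
  values <- if (inherits(pheno, "voxel_qt")) pheno$values else as.matrix(pheno)
  ids <- rownames(values)
  if (inherits(a, "grm") && !is.null(ids) &&
      !identical(as.character(ids), as.character(a$samples))) {
    mism <- setdiff(ids, a$samples)
    stop_herimap(
      sprintf("sample IDs of phenotype and GRM differ (e.g. %s)",
              paste(head(c(mism, setdiff(a$samples, ids)), 3), collapse = ", ")),
      "herimap_id_error")
  }
  prep <- reml_prep(a, x)
  traits <- colnames(values) %||% as.character(seq_len(ncol(values)))
  rows <- vector("list", ncol(values))
  for (j in seq_len(ncol(values))) {
    y <- values[, j]
    vy <- var(y)
    if (!all(is.finite(y)) || vy == 0) {
      rows[[j]] <- tibble(
        trait = traits[j], sigma_g2 = NA_real_, sigma_e2 = NA_real_,
        h2 = NA_real_, h2_se = NA_real_, loglik_full = NA_real_,
        loglik_null = NA_real_, lrt = NA_real_, p_value = NA_real_,
        n_iter = NA_integer_, converged = NA, constrained = NA,
        status = if (vy == 0 && all(is.finite(y))) "failed_constant"
                 else "failed_nonfinite")
      next
    }
    yt <- drop(crossprod(prep$u, y))
    f <- fit_reml_rotated(yt, prep, vy, opts)
    rows[[j]] <- tibble(
      trait = traits[j], sigma_g2 = f$sigma_g2, sigma_e2 = f$sigma_e2,
      h2 = f$h2, h2_se = f$h2_se, loglik_full = f$loglik_full,
      loglik_null = f$loglik_null, lrt = f$lrt, p_value = f$p_value,
      n_iter = f$n_iter, converged = f$converged, constrained = f$constrained,
      status = "ok")
  }
  list_rbind(rows)
}

#' Write a batch of heritability results as TSV
#'
#' One row per trait, mirroring the content of GCTA `.hsq` output.
#' @param results tibble from [fit_reml_batch()]
#' @param path output file
#' @export
write_reml_tsv <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
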