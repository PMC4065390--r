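# The Poisson additive-model engine:
#   log lambda(d) = beta0 + s1(x_d) + I(d special) * s2(x_d),
# x_d the day index normalized to [0, 1]. s1 is sum-to-zero constrained (the
# intercept carries the level); s2 is identified by the indicator and carries
# the weekend log-ratio directly. Fitting is penalized IRLS; smoothing
# parameters minimize GCV. All per-iteration algebra is O(n * bandwidth^2):
# the design is stored as a sparse matrix plus a rank-one centering
# correction, and only the (p x p) normal equations are ever densified.

#' Control parameters for the birthdate GAM
#'
#' @param max_rank_s1 Basis rank of the trend smooth \eqn{s_1}. Default
#'   `min(ceiling(2 * years_covered), 200)`: two degrees of freedom per year
#'   leaves room for annual seasonality, while 200 keeps multi-decade series
#'   tractable.
#' @param rank_s2 Basis rank of the weekend smooth \eqn{s_2} (default 10; it
#'   models a secular, gradual change, so low rank suffices).
#' @param basis `"cubic_ps"` (cubic penalized regression splines, default) or
#'   `"thin_plate"` (reduced-rank thin-plate regression splines).
#' @param sp Optional fixed smoothing parameters (named `s1`, `s2`), skipping
#'   GCV selection.
#' @param sp_lower,sp_upper Bounds of the smoothing-parameter search, on the
#'   log10 scale.
#' @param coarse_step Log10 step of the coarse GCV grid.
#' @param refine_cycles Coordinate golden-section refinement passes after the
#'   coarse grid.
#' @param tol Relative deviance-change convergence tolerance of the IRLS loop.
#' @param max_iter Maximum IRLS iterations.
#' @return A list of class `gam_control`.
#' @export
gam_control <- function(max_rank_s1 = NULL, rank_s2 = 10L,
                        basis = c("cubic_ps", "thin_plate"),
                        sp = NULL,
                        sp_lower = -8, sp_upper = 8,
                        coarse_step = 3, refine_cycles = 2L,
                        tol = 1e-8, max_iter = 200L) {
  basis <- match.arg(basis)
  if (tol <= 0) bg_abort("`tol` must be positive.", "birthgam_config_error")
  if (!is.null(rank_s2) && rank_s2 < 3) {
    bg_abort("Ranks must be >= 3.", "birthgam_config_error")
  }
  structure(
    list(max_rank_s1 = max_rank_s1, rank_s2 = as.integer(rank_s2),
         basis = basis, sp = sp,
         sp_lower = sp_lower, sp_upper = sp_upper,
         coarse_step = coarse_step, refine_cycles = as.integer(refine_cycles),
         tol = tol, max_iter = as.integer(max_iter)),
    class = "gam_control"
  )
}

default_rank_s1 <- function(n_days) {
  years <- n_days / 365.25
  max(10L, min(as.integer(ceiling(2 * years)), 200L))
}

#' Build design and penalty matrices for the birthdate GAM
#'
#' Block 1 is the intercept plus the sum-to-zero-constrained trend basis
#' (columns of the constrained block sum to zero over the fitting dates);
#' block 2 is the weekend basis with rows multiplied by the special-day
#' indicator (identically zero rows on ordinary weekdays). One penalty matrix
#' per smooth; each penalty's null space contains the linear functions.
#'
#' @param series A [as_birth_series()] tibble (`date`, `count`, `special`).
#' @param control A [gam_control()].
#' @return A list of class `birth_design`; see [design_matrix()] for the
#'   dense view.
#' @export
build_design <- function(series, control = gam_control()) {
  series <- as_birth_series(series)
  n <- nrow(series)
  if (n < 10) bg_abort("Series too short to fit (n < 10).",
                       "birthgam_data_error")
  q1 <- control$max_rank_s1 %||% default_rank_s1(n)
  q2 <- control$rank_s2
  has_s2 <- any(series$special == 1)

  # total coefficients: intercept + (q1 - 1) constrained + q2
  need <- q1 + ifelse(has_s2, q2, 0)
  if (n < need) {
    shrink <- n / need
    q1 <- max(4L, as.integer(floor(q1 * shrink * 0.9)))
    q2 <- max(4L, min(q2, as.integer(floor(q2 * shrink * 0.9)), q1))
    warning(sprintf(
      "Series shorter than requested ranks; reduced to s1 rank %d, s2 rank %d.",
      q1, q2))
  }
  if (q1 < 4) bg_abort("Series too short for any smooth fit.",
                       "birthgam_data_error")

  x <- if (n == 1) 0 else (seq_len(n) - 1) / (n - 1)
  b1 <- make_smooth_basis(control$basis, q1, x)
  X1_full <- eval_basis(b1, x)
  con <- absorb_constraint(b1, X1_full)
  Xs1 <- Matrix::Matrix(con$X, sparse = TRUE)

  if (has_s2) {
    b2 <- make_smooth_basis(control$basis, q2, x)
    X2 <- eval_basis(b2, x) * series$special   # zero rows off the indicator
    Xs2 <- Matrix::Matrix(X2, sparse = TRUE)
    Xs <- cbind(Xs1, Xs2)
    u <- c(con$u, numeric(q2))
  } else {
    b2 <- NULL
    Xs <- Xs1
    u <- con$u
  }

  p1 <- ncol(Xs1)
  p2 <- if (has_s2) q2 else 0L
  idx_s1 <- 1L + seq_len(p1)
  idx_s2 <- if (has_s2) 1L + p1 + seq_len(p2) else integer(0)

  structure(
    list(n = n, x = x, special = series$special, date0 = series$date[1],
         Xs = Xs, u = u, p = 1L + p1 + p2,
         idx = list(intercept = 1L, s1 = idx_s1, s2 = idx_s2),
         S = list(s1 = con$penalty,
                  s2 = if (has_s2) b2$penalty else NULL),
         basis1 = b1, basis2 = b2, keep1 = con$keep,
         has_s2 = has_s2, rank = c(s1 = q1, s2 = if (has_s2) q2 else 0L)),
    class = "birth_design"
  )
}

#' Dense model matrix of a design (intercept, constrained s1 block, s2 block)
#'
#' Mostly useful for inspection and testing; fitting never forms this matrix.
#'
#' @param design A [build_design()] object.
#' @param rows Optional row subset.
#' @return A dense numeric matrix with `design$p` columns.
#' @export
design_matrix <- function(design, rows = NULL) {
  rows <- rows %||% seq_len(design$n)
  Xc <- as.matrix(design$Xs[rows, , drop = FALSE])
  Xc <- sweep(Xc, 2, design$u, "-")
  cbind(`(Intercept)` = 1, Xc)
}

# Embed the per-term penalties, scaled by sp, into the full p x p matrix.
penalty_matrix <- function(design, sp) {
  S <- matrix(0, design$p, design$p)
  S[design$idx$s1, design$idx$s1] <- sp[["s1"]] * design$S$s1
  if (design$has_s2) {
    S[design$idx$s2, design$idx$s2] <- sp[["s2"]] * design$S$s2
  }
  S
}

# Restrict a design to a subset of rows (used to verify that zero weights and
# row deletion are equivalent, and for other diagnostics).
subset_design_rows <- function(design, rows) {
  d <- design
  d$Xs <- design$Xs[rows, , drop = FALSE]
  d$x <- design$x[rows]
  d$special <- design$special[rows]
  d$n <- length(rows)
  d
}

poisson_deviance <- function(y, mu, w = NULL) {
  w <- w %||% rep(1, length(y))
  term <- ifelse(y > 0, y * log(y / mu), 0) - (y - mu)
  2 * sum(w * term)
}

#' Penalized iteratively reweighted least squares for the Poisson GAM
#'
#' Maximizes the penalized Poisson log-likelihood at fixed smoothing
#' parameters. The working model is solved through the sparse design plus
#' rank-one centering correction, so each iteration costs O(n) plus one dense
#' p x p solve. Step halving enforces a monotone decrease of penalized
#' deviance across accepted iterations; non-convergence is reported in the
#' result, never silently.
#'
#' @param design A [build_design()] object.
#' @param counts Non-negative integer counts, length `design$n`.
#' @param sp Named non-negative smoothing parameters (`s1`, and `s2` when the
#'   design has a special-day block).
#' @param weights Optional non-negative prior observation weights (0/1 weights
#'   implement refit-after-removal).
#' @param control A [gam_control()] (only `tol`/`max_iter` are used here).
#' @param init Optional initial linear predictor (warm start); default is the
#'   working response `log(count + 0.5)`.
#' @return A list with `coefficients`, `eta`, `mu`, `deviance`, `edf`
#'   (per-term and total), `trA`, `n_eff`, `converged`, `iter`.
#' @export
fit_pirls <- function(design, counts, sp, weights = NULL,
                      control = gam_control(), init = NULL) {
  stopifnot(inherits(design, "birth_design"))
  y <- as.numeric(counts)
  if (length(y) != design$n) {
    bg_abort("`counts` length does not match design.", "birthgam_data_error")
  }
  if (any(y < 0) || anyNA(y)) {
    bg_abort("Counts must be non-negative and complete.",
             "birthgam_data_error")
  }
  sp <- normalize_sp(design, sp)
  w_prior <- weights %||% rep(1, design$n)
  if (any(w_prior < 0)) bg_abort("Weights must be non-negative.",
                                 "birthgam_data_error")
  n_eff <- sum(w_prior > 0)

  Xs <- design$Xs
  u <- design$u
  S <- penalty_matrix(design, sp)
  p <- design$p

  eta <- if (is.null(init)) log(y + 0.5) else pmin(init, 35)
  mu <- exp(eta)
  beta <- NULL
  dev <- poisson_deviance(y, mu, w_prior)
  pen <- 0
  converged <- FALSE
  ridge_used <- FALSE
  iter <- 0L
  H <- NULL

  linpred <- function(b) {
    as.numeric(Xs %*% b[-1]) - sum(u * b[-1]) + b[1]
  }

  for (iter in seq_len(control$max_iter)) {
    wv <- w_prior * mu                     # IRLS weights, log link
    z <- eta + (y - mu) / mu               # working response
    sw <- sum(wv)
    tM <- as.numeric(Matrix::crossprod(Xs, wv))
    G <- as.matrix(Matrix::crossprod(Xs * sqrt(wv)))
    H <- matrix(0, p, p)
    H[1, 1] <- sw
    h1 <- tM - sw * u
    H[1, -1] <- h1
    H[-1, 1] <- h1
    H[-1, -1] <- G - tcrossprod(tM, u) - tcrossprod(u, tM) +
      sw * tcrossprod(u)
    wz <- wv * z
    b_rhs <- c(sum(wz), as.numeric(Matrix::crossprod(Xs, wz)) - u * sum(wz))

    A <- H + S
    ch <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(ch)) {
      ridge_used <- TRUE
      ridge <- 1e-7 * mean(diag(A))
      ch <- tryCatch(chol(A + diag(ridge, p)), error = function(e) NULL)
      if (is.null(ch)) {
        bg_abort("Singular working system; ridge fallback also failed.",
                 "birthgam_numeric_error")
      }
    }
    beta_new <- backsolve(ch, forwardsolve(t(ch), b_rhs))

    # step halving: accept only steps that do not increase the penalized
    # deviance (beyond numerical slack)
    pen_dev <- function(b) {
      e <- pmin(linpred(b), 35)            # guard against transient overflow
      poisson_deviance(y, exp(e), w_prior) + as.numeric(t(b) %*% S %*% b)
    }
    target <- dev + pen
    step_ok <- FALSE
    b_try <- beta_new
    for (h in 0:12) {
      cand <- pen_dev(b_try)
      if (is.finite(cand) && cand <= target * (1 + 1e-10) + 1e-10) {
        step_ok <- TRUE
        break
      }
      if (is.null(beta)) break             # first step: accept best effort
      b_try <- (b_try + beta) / 2
    }
    if (!step_ok && !is.null(beta)) {
      converged <- TRUE                    # cannot improve further
      break
    }
    beta <- b_try
    eta <- pmin(linpred(beta), 35)
    mu <- exp(eta)
    dev_new <- poisson_deviance(y, mu, w_prior)
    pen <- as.numeric(t(beta) %*% S %*% beta)
    if (abs(dev_new - dev) < control$tol * (abs(dev_new) + 0.1)) {
      dev <- dev_new
      converged <- TRUE
      break
    }
    dev <- dev_new
  }
  if (ridge_used) warning("Working system was singular; a small ridge was added.")

  # effective degrees of freedom: diag of (H + S)^{-1} H at convergence
  A <- H + S
  Ainv_H <- tryCatch(solve(A, H), error = function(e) {
    solve(A + diag(1e-8 * mean(diag(A)), p), H)
  })
  lev <- diag(Ainv_H)
  edf <- c(
    intercept = lev[1],
    s1 = sum(lev[design$idx$s1]),
    s2 = if (design$has_s2) sum(lev[design$idx$s2]) else 0
  )

  list(coefficients = beta, eta = eta, mu = mu,
       deviance = dev, penalty = pen,
       edf = edf, edf_total = sum(lev), trA = sum(lev),
       n_eff = n_eff, sp = sp,
       converged = converged, iter = iter)
}

normalize_sp <- function(design, sp) {
  if (is.null(sp)) bg_abort("Smoothing parameters required.",
                            "birthgam_config_error")
  if (is.null(names(sp))) {
    names(sp) <- c("s1", "s2")[seq_along(sp)]
  }
  if (!"s1" %in% names(sp)) bg_abort("`sp` needs an `s1` entry.",
                                     "birthgam_config_error")
  if (design$has_s2 && !"s2" %in% names(sp)) {
    bg_abort("`sp` needs an `s2` entry for this design.",
             "birthgam_config_error")
  }
  if (any(unlist(sp) < 0)) bg_abort("Smoothing parameters must be >= 0.",
                                    "birthgam_config_error")
  sp
}

gcv_score <- function(fit) {
  n <- fit$n_eff
  denom <- n - fit$trA
  if (denom <= 0) return(Inf)
  n * fit$deviance / denom^2
}

#' Select smoothing parameters by generalized cross-validation
#'
#' Minimizes \eqn{GCV(\rho) = n D(\rho) / (n - \mathrm{tr} A(\rho))^2}
#' (D the Poisson deviance, A the influence matrix) over a coarse log10 grid
#' followed by coordinate-wise golden-section refinement; IRLS fits are
#' warm-started from the previous candidate, and the full profile of
#' evaluated candidates is returned.
#'
#' @inheritParams fit_pirls
#' @param control A [gam_control()] providing the search bounds/resolution.
#' @return A list with `sp` (the minimizer), `gcv`, and `profile` (a tibble
#'   of all evaluated candidates).
#' @export
select_smoothing <- function(design, counts, control = gam_control(),
                             weights = NULL) {
  loose <- control
  loose$tol <- max(control$tol, 1e-7)
  profile <- list()
  any_ok <- FALSE
  warm <- NULL

  eval_gcv <- function(l1, l2) {
    sp <- c(s1 = 10^l1)
    if (design$has_s2) sp <- c(sp, s2 = 10^l2)
    f <- tryCatch(
      suppressWarnings(fit_pirls(design, counts, sp, weights, loose,
                                 init = warm)),
      error = function(e) NULL
    )
    if (is.null(f)) {
      profile[[length(profile) + 1L]] <<-
        tibble(log10_sp_s1 = l1, log10_sp_s2 = l2, gcv = Inf,
               edf = NA_real_, converged = FALSE)
      return(Inf)
    }
    g <- gcv_score(f)
    any_ok <<- any_ok || f$converged
    if (f$converged) warm <<- f$eta
    profile[[length(profile) + 1L]] <<-
      tibble(log10_sp_s1 = l1, log10_sp_s2 = l2, gcv = g,
             edf = f$edf_total, converged = f$converged)
    g
  }

  lo <- control$sp_lower
  hi <- control$sp_upper
  grid <- seq(lo, hi, by = control$coarse_step)
  if (grid[length(grid)] < hi) grid <- c(grid, hi)

  best <- c(l1 = grid[1], l2 = grid[1])
  best_g <- Inf
  if (design$has_s2) {
    for (l1 in grid) for (l2 in grid) {
      g <- eval_gcv(l1, l2)
      if (g < best_g) { best_g <- g; best <- c(l1 = l1, l2 = l2) }
    }
  } else {
    for (l1 in grid) {
      g <- eval_gcv(l1, NA)
      if (g < best_g) { best_g <- g; best <- c(l1 = l1, l2 = NA) }
    }
  }

  # coordinate golden-section refinement around the coarse minimum
  gold <- function(f, a, b, tol = 0.05) {
    phi <- (sqrt(5) - 1) / 2
    c1 <- b - phi * (b - a); c2 <- a + phi * (b - a)
    f1 <- f(c1); f2 <- f(c2)
    while (b - a > tol) {
      if (f1 <= f2) { b <- c2; c2 <- c1; f2 <- f1
        c1 <- b - phi * (b - a); f1 <- f(c1)
      } else { a <- c1; c1 <- c2; f1 <- f2
        c2 <- a + phi * (b - a); f2 <- f(c2) }
    }
    if (f1 <= f2) c1 else c2
  }
  span <- control$coarse_step
  for (cycle in seq_len(control$refine_cycles)) {
    best["l1"] <- gold(function(l) eval_gcv(l, best[["l2"]]),
                       max(lo, best[["l1"]] - span),
                       min(hi, best[["l1"]] + span))
    if (design$has_s2) {
      best["l2"] <- gold(function(l) eval_gcv(best[["l1"]], l),
                         max(lo, best[["l2"]] - span),
                         min(hi, best[["l2"]] + span))
    }
    span <- span / 2
  }
  best_g <- eval_gcv(best[["l1"]], best[["l2"]])

  if (!any_ok) {
    bg_abort("No smoothing-parameter candidate converged.",
             "birthgam_numeric_error")
  }
  sp <- c(s1 = 10^best[["l1"]])
  if (design$has_s2) sp <- c(sp, s2 = 10^best[["l2"]])
  list(sp = sp, gcv = best_g, profile = bind_rows(profile))
}
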