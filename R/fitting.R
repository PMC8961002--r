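# Multi-start bounded nonlinear least squares with variable projection over
# the linear signal fractions, minima enumeration, and BIC model comparison.

# nonlinear parameter layout per model (names double as start/bound keys)
.nl_params <- function(model) {
  switch(model,
    SANDI = c("De", "Dn", "Rs"),
    SMEX = c("De", "Dn", "rn", "fn_rel"),
    SANDIX = ,
    eSANDIX = c("De", "Dn", "rn", "fn_rel", "Rs"))
}

# fitting bounds / random-start ranges (diffusivities 0-3 um^2/ms, exchange
# rate 0-1 1/ms, soma radius 0-20 um, relative exchanging fraction 0-100%)
.nl_bounds <- function(names) {
  lower <- c(De = 0, Dn = 0, rn = 0, fn_rel = 0, Rs = 0)[names]
  upper <- c(De = 3, Dn = 3, rn = 1, fn_rel = 1, Rs = 20)[names]
  list(lower = unname(lower), upper = unname(upper))
}

# basis of compartment signals for the linear (variable-projection) stage;
# columns are unit-amplitude compartment signals, all equal to 1 at b = 0
.basis_matrix <- function(model, theta, proto, quad, n_ramp = 64) {
  b <- proto$b; Delta <- proto$Delta; delta <- proto$delta
  th <- as.list(theta)
  sphere_col <- function(Rs) {
    key <- paste(Delta, delta)
    uk <- unique(key)
    Ds <- vapply(uk, function(k) {
      i <- match(k, key)
      sphere_diffusivity_gpa(Delta[i], delta[i], max(Rs, 1e-4), 2)
    }, numeric(1))
    exp(-b * Ds[match(key, uk)])
  }
  cols <- switch(model,
    SANDI = list(
      gauss = gaussian_signal(b, th$De),
      stick = stick_powder_signal(b, th$Dn),
      sphere = sphere_col(th$Rs),
      fim = rep(1, length(b))),
    SMEX = list(
      exch = stick_exchange_powder(b, Delta, delta, th$Dn, th$De,
                                   fn = th$fn_rel, rn = th$rn, quad = quad,
                                   n_ramp = n_ramp),
      fim = rep(1, length(b))),
    SANDIX = list(
      exch = stick_exchange_powder(b, Delta, delta, th$Dn, th$De,
                                   fn = th$fn_rel, rn = th$rn, quad = quad,
                                   n_ramp = n_ramp),
      sphere = sphere_col(th$Rs),
      fim = rep(1, length(b))),
    eSANDIX = list(
      exch = stick_exchange_powder(b, Delta, delta, th$Dn, th$De,
                                   fn = th$fn_rel, rn = th$rn, quad = quad,
                                   n_ramp = n_ramp),
      sphere = sphere_col(th$Rs),
      stick = stick_powder_signal(b, th$Dn),
      fim = rep(1, length(b))))
  B <- do.call(cbind, cols)
  colnames(B) <- names(cols)
  B
}

#' Non-negative compartment amplitudes by variable projection
#'
#' Inner linear stage of [fit_model()]: given the matrix of unit-amplitude
#' compartment basis signals, solves the non-negative least-squares problem
#' for the amplitudes, optionally capping the immobile-water fraction.  If
#' the basis is numerically rank deficient (for example a duplicated
#' column), a small ridge is added and the result is flagged.
#'
#' @param B Basis matrix (rows = measurements, columns = compartments); if a
#'   column is named `"fim"` its fraction is capped at `fim_max`.
#' @param y Observed signals.
#' @param fim_max Cap on the immobile fraction (default 0.05).
#' @return List with `amplitudes` (non-negative, same order as columns),
#'   `fractions` (normalized to sum 1), `S0` (amplitude sum), `residuals`,
#'   and logical flags `rank_deficient`, `fim_capped`.
#' @export
varpro_weights <- function(B, y, fim_max = 0.05) {
  B <- as.matrix(B)
  rank_def <- qr(B)$rank < ncol(B)
  solve_nnls <- function(A, rhs) {
    if (rank_def) {           # ridge fallback keeps the problem well posed
      lam <- 1e-8 * max(colSums(A^2))
      A <- rbind(A, sqrt(lam) * diag(ncol(A)))
      rhs <- c(rhs, numeric(ncol(A)))
    }
    pracma::lsqnonneg(A, rhs)$x
  }
  a <- solve_nnls(B, y)
  fim_capped <- FALSE
  j <- match("fim", colnames(B))
  if (!is.na(j) && sum(a) > 0 && a[j] > fim_max * sum(a)) {
    # enforce a_fim = fim_max * sum(a): substitute into the remaining columns
    fim_capped <- TRUE
    scale <- fim_max / (1 - fim_max)
    Bred <- B[, -j, drop = FALSE] + scale * B[, j]
    ared <- solve_nnls(Bred, y)
    a <- numeric(ncol(B))
    a[-j] <- ared
    a[j] <- scale * sum(ared)
  }
  S0 <- sum(a)
  list(amplitudes = a,
       fractions = if (S0 > 0) a / S0 else a,
       S0 = S0,
       residuals = y - drop(B %*% a),
       rank_deficient = rank_def,
       fim_capped = fim_capped)
}

# residual function for the nonlinear stage; non-finite basis values give a
# large finite cost rather than an error
.vp_residuals <- function(theta, model, proto, y, quad, n_ramp = 64) {
  B <- tryCatch(.basis_matrix(model, theta, proto, quad, n_ramp),
                error = function(e) NULL)
  if (is.null(B) || !all(is.finite(B))) return(rep(1e6, length(y)))
  varpro_weights(B, y)$residuals
}

# assemble gm_params from nonlinear parameters + varpro fractions
.assemble_params <- function(model, theta, fr) {
  th <- as.list(theta)
  # a soma compartment fitted with Rs at the lower bound is kept representable
  if (!is.null(th$Rs)) th$Rs <- max(th$Rs, 1e-4)
  switch(model,
    SANDI = gm_params("SANDI", fe = fr[["gauss"]], fn = fr[["stick"]],
                      fs = fr[["sphere"]], fim = fr[["fim"]],
                      De = th$De, Dn = th$Dn, Rs = th$Rs),
    SMEX = gm_params("SMEX",
                     fe = fr[["exch"]] * (1 - th$fn_rel),
                     fn = fr[["exch"]] * th$fn_rel, fim = fr[["fim"]],
                     De = th$De, Dn = th$Dn,
                     tau_n = if (th$rn > 0) 1 / th$rn else Inf),
    SANDIX = gm_params("SANDIX",
                       fe = fr[["exch"]] * (1 - th$fn_rel),
                       fn = fr[["exch"]] * th$fn_rel,
                       fs = fr[["sphere"]], fim = fr[["fim"]],
                       De = th$De, Dn = th$Dn,
                       tau_n = if (th$rn > 0) 1 / th$rn else Inf,
                       Rs = th$Rs),
    eSANDIX = gm_params("eSANDIX",
                        fe = fr[["exch"]] * (1 - th$fn_rel),
                        fn = fr[["exch"]] * th$fn_rel,
                        fn_imp = fr[["stick"]],
                        fs = fr[["sphere"]], fim = fr[["fim"]],
                        De = th$De, Dn = th$Dn,
                        tau_n = if (th$rn > 0) 1 / th$rn else Inf,
                        Rs = th$Rs))
}

#' Fit a gray-matter model by multi-start variable-projection least squares
#'
#' Bounded trust-region (Levenberg-Marquardt) least squares from random
#' initializations.  The nonlinear parameters are the diffusivities, the
#' exchange rate (exchange models, bounded in \[0, 1\] 1/ms and reported as
#' `tau_n = 1/rn`), the soma radius and the relative fraction of the
#' exchanging pair; the linear signal fractions (and the overall amplitude
#' S0) are eliminated at every iteration by non-negative linear least
#' squares ([varpro_weights()]).  Converged solutions are clustered into
#' basins ([enumerate_minima()]) and ranked by cost.
#'
#' @param tab A `"powder_signal"` data frame (the data).
#' @param model One of `"SANDI"`, `"SMEX"`, `"SANDIX"`, `"eSANDIX"`.
#' @param n_starts Number of random initializations (default 50; increase
#'   towards 1000 for production fits).
#' @param seed RNG seed making the fit bit-reproducible.
#' @param quad Powder quadrature rule.
#' @param basin_tol Relative parameter tolerance for basin clustering.
#' @param n_ramp Ramp substeps for the exchange engine during fitting
#'   (default 32; relative signal accuracy ~1e-6, ample below any noise
#'   floor).
#' @return An object of class `"gm_fit"`: list with `best` ([gm_params()]),
#'   `cost` (sum of squared residuals), `bic`, `minima` (data frame of
#'   distinct local minima with parameters, cost, BIC and basin size),
#'   `n_starts`, `seed`, `model`, `n_obs`, `k` (free parameter count) and
#'   the fitted `fractions`/`S0`.
#' @export
fit_model <- function(tab, model, n_starts = 50, seed = 1,
                      quad = powder_quadrature(), basin_tol = 0.01,
                      n_ramp = 32) {
  model <- match.arg(model, .GM_MODELS)
  if (!all(is.finite(tab$S))) stop("non-finite signals in data")
  if (model != "SANDI" && length(unique(tab$Delta)) < 2)
    warning("exchange models are poorly constrained by a single diffusion time")
  y <- tab$S
  n <- length(y)
  pn <- .nl_params(model)
  bd <- .nl_bounds(pn)
  set.seed(seed)
  starts <- matrix(runif(n_starts * length(pn), rep(bd$lower, each = n_starts),
                         rep(bd$upper, each = n_starts)),
                   nrow = n_starts, dimnames = list(NULL, pn))
  sols <- vector("list", n_starts)
  for (i in seq_len(n_starts)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = starts[i, ], lower = bd$lower, upper = bd$upper,
        fn = .vp_residuals, model = model, proto = tab, y = y, quad = quad,
        n_ramp = n_ramp,
        control = minpack.lm::nls.lm.control(
          ftol = 1e-12, ptol = 1e-12, maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    theta <- setNames(coef(fit), pn)
    sols[[i]] <- list(theta = theta, cost = sum(fit$fvec^2))
  }
  sols <- Filter(Negate(is.null), sols)
  if (length(sols) == 0) stop("all starts failed; degenerate data?")
  thetas <- do.call(rbind, lapply(sols, `[[`, "theta"))
  costs <- vapply(sols, `[[`, numeric(1), "cost")
  basins <- enumerate_minima(thetas, costs, tol = basin_tol)
  # number of free parameters: nonlinear + linear amplitudes (incl. S0 scale)
  k <- length(pn) + ncol(.basis_matrix(model, thetas[1, ], tab, quad, n_ramp))
  bic_of <- function(cost) n * log(max(cost, 1e-300) / n) + k * log(n)
  min_list <- lapply(seq_len(nrow(basins$representatives)), function(j) {
    th <- basins$representatives[j, ]
    B <- .basis_matrix(model, th, tab, quad, n_ramp)
    vp <- varpro_weights(B, y)
    fr <- setNames(vp$fractions, colnames(B))
    list(theta = th, cost = basins$costs[j], bic = bic_of(basins$costs[j]),
         size = basins$sizes[j],
         params = .assemble_params(model, th, fr), fractions = fr, S0 = vp$S0)
  })
  best <- min_list[[1]]
  minima_df <- do.call(rbind, lapply(min_list, function(m)
    data.frame(t(m$theta), cost = m$cost, bic = m$bic, basin_size = m$size)))
  structure(list(best = best$params, theta = best$theta, cost = best$cost,
                 bic = best$bic, fractions = best$fractions, S0 = best$S0,
                 minima = minima_df, minima_detail = min_list,
                 n_starts = n_starts, seed = seed, model = model,
                 n_obs = n, k = k),
            class = "gm_fit")
}

#' @export
print.gm_fit <- function(x, ...) {
  cat(sprintf("%s fit: %d starts, %d distinct minima, cost = %.4g, BIC = %.2f\n",
              x$model, x$n_starts, nrow(x$minima), x$cost, x$bic))
  print(x$best)
  invisible(x)
}

#' Cluster converged solutions into distinct local minima
#'
#' Greedy clustering in order of increasing cost: a solution joins an
#' existing basin when every parameter agrees with the basin representative
#' within the relative tolerance (parameters near zero are compared on a
#' small absolute floor).
#'
#' @param thetas Matrix of converged parameter vectors (rows = starts).
#' @param costs Final costs, one per row.
#' @param tol Relative per-parameter agreement tolerance (default 1%).
#' @return List with `representatives` (matrix, best solution per basin,
#'   sorted by cost), `costs`, `sizes`.
#' @export
enumerate_minima <- function(thetas, costs, tol = 0.01) {
  thetas <- as.matrix(thetas)
  o <- order(costs)
  thetas <- thetas[o, , drop = FALSE]; costs <- costs[o]
  reps <- thetas[1, , drop = FALSE]
  rep_costs <- costs[1]; sizes <- 1L
  if (nrow(thetas) > 1) for (i in 2:nrow(thetas)) {
    th <- thetas[i, ]
    hit <- 0L
    for (j in seq_len(nrow(reps))) {
      ref <- reps[j, ]
      if (all(abs(th - ref) <= tol * pmax(abs(ref), 0.05))) { hit <- j; break }
    }
    if (hit > 0L) sizes[hit] <- sizes[hit] + 1L
    else {
      reps <- rbind(reps, th); rep_costs <- c(rep_costs, costs[i])
      sizes <- c(sizes, 1L)
    }
  }
  list(representatives = reps, costs = rep_costs, sizes = sizes)
}

#' Compare fitted models by BIC
#'
#' Ranks a set of [fit_model()] results fitted to the same data by
#' `BIC = n ln(cost/n) + k ln(n)`.  Differences above 10 are flagged as
#' significant and below 1 as indistinguishable, following common model
#' selection practice.
#'
#' @param fits A (named) list of `"gm_fit"` objects on identical data.
#' @return Data frame with model, k, cost, BIC, `delta_bic` relative to the
#'   best model, and `significant` / `indistinguishable` flags.
#' @export
compare_models <- function(fits) {
  if (length(unique(vapply(fits, `[[`, numeric(1), "n_obs"))) != 1)
    stop("fits must use the same data")
  bic <- vapply(fits, `[[`, numeric(1), "bic")
  out <- data.frame(
    model = vapply(fits, `[[`, character(1), "model"),
    k = vapply(fits, `[[`, numeric(1), "k"),
    cost = vapply(fits, `[[`, numeric(1), "cost"),
    bic = bic,
    delta_bic = bic - min(bic))
  out$significant <- out$delta_bic > 10
  out$indistinguishable <- out$delta_bic < 1
  out[order(out$bic), ]
}
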