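# Assembly of the four powder-averaged gray-matter signal models and the
# functional signal analyses (apparent power-law exponent, time-dependence
# sign classification, powder DKI summary).

.GM_MODELS <- c("SANDI", "SMEX", "SANDIX", "eSANDIX")

#' Gray-matter model parameters
#'
#' Parameter container for the four models.  Fractions are signal fractions
#' of S0 and must be non-negative and sum to 1 over the compartments the
#' model includes; fields irrelevant to a model must be left at 0 (or `NA`
#' for `tau_n`/`Rs`).  The permeable and impermeable sticks of eSANDIX share
#' the diffusivity `Dn`.
#'
#' @param model One of `"SANDI"`, `"SMEX"`, `"SANDIX"`, `"eSANDIX"`.
#' @param fe,fn,fs,fim Extracellular, (exchanging) neurite, soma and
#'   immobile signal fractions.
#' @param fn_imp Impermeable-stick signal fraction (eSANDIX only).
#' @param De,Dn Extracellular and neurite diffusivities, um^2/ms.
#' @param tau_n Mean neurite residence time, ms (exchange models); the
#'   neurite escape rate is `rn = 1/tau_n`.
#' @param Rs Soma radius, um (soma models).
#' @param D0 Intra-soma free diffusivity, um^2/ms, fixed at 2 by default.
#' @return An object of class `"gm_params"`.
#' @export
gm_params <- function(model, fe = 0, fn = 0, fs = 0, fim = 0, fn_imp = 0,
                      De = 1, Dn = 1, tau_n = NA_real_, Rs = NA_real_, D0 = 2) {
  model <- match.arg(model, .GM_MODELS)
  fr <- c(fe = fe, fn = fn, fs = fs, fim = fim, fn_imp = fn_imp)
  if (any(fr < 0)) stop("signal fractions must be non-negative")
  has_soma <- model %in% c("SANDI", "SANDIX", "eSANDIX")
  has_exch <- model %in% c("SMEX", "SANDIX", "eSANDIX")
  if (!has_soma && fs > 0) stop(sprintf("model %s has no soma compartment", model))
  if (model != "eSANDIX" && fn_imp > 0)
    stop(sprintf("model %s has no impermeable-stick compartment", model))
  if (has_exch && (is.na(tau_n) || tau_n <= 0))
    stop("exchange models require a positive 'tau_n' (Inf for no exchange)")
  if (has_soma && fs > 0 && (!is.finite(Rs) || Rs <= 0))
    stop("a positive 'Rs' is required when fs > 0")
  if (abs(sum(fr) - 1) > 1e-8)
    stop("signal fractions must sum to 1")
  structure(list(model = model, fe = fe, fn = fn, fs = fs, fim = fim,
                 fn_imp = fn_imp, De = De, Dn = Dn, tau_n = tau_n,
                 Rs = Rs, D0 = D0),
            class = "gm_params")
}

#' @export
print.gm_params <- function(x, ...) {
  cat(sprintf("%s parameters:\n", x$model))
  cat(sprintf("  fractions: fe = %.3f, fn = %.3f, fn_imp = %.3f, fs = %.3f, fim = %.3f\n",
              x$fe, x$fn, x$fn_imp, x$fs, x$fim))
  cat(sprintf("  De = %.3f, Dn = %.3f um^2/ms", x$De, x$Dn))
  if (is.finite(x$tau_n)) cat(sprintf(", tau_n = %.2f ms", x$tau_n))
  if (is.finite(x$Rs)) cat(sprintf(", Rs = %.2f um", x$Rs))
  cat("\n")
  invisible(x)
}

#' Powder-averaged model signal over an acquisition protocol
#'
#' Evaluates the chosen model row-by-row over the protocol:
#' * SANDI: `fe exp(-b De) + fn stick(b, Dn) + fs exp(-b Ds(Delta, delta, Rs)) + fim`
#' * SMEX: powder-averaged Karger stick-extracellular block of weight
#'   `fe + fn` (internal fraction `fn/(fe+fn)`, escape rate `1/tau_n`) `+ fim`
#' * SANDIX: SMEX plus the soma term
#' * eSANDIX: SANDIX plus an impermeable stick sharing `Dn`
#'
#' The soma term uses the finite-pulse Gaussian-phase diffusivity at all b.
#'
#' @param proto An `"acq_protocol"` data frame (or any data frame with
#'   columns `b`, `Delta`, `delta`).
#' @param params A [gm_params()] object.
#' @param quad Powder quadrature rule for the exchange models.
#' @return A signal table of class `"powder_signal"`: a data frame with
#'   columns `b`, `Delta`, `delta`, `S` and provenance `"model"`.
#' @export
model_signal <- function(proto, params, quad = powder_quadrature()) {
  stopifnot(inherits(params, "gm_params"))
  b <- proto$b; Delta <- proto$Delta; delta <- proto$delta
  soma_term <- function() {
    if (params$fs == 0) return(0)
    key <- paste(Delta, delta)
    Ds <- vapply(unique(key), function(k) {
      i <- match(k, key)
      sphere_diffusivity_gpa(Delta[i], delta[i], params$Rs, params$D0)
    }, numeric(1))
    exp(-b * Ds[match(key, unique(key))])
  }
  S <- switch(params$model,
    SANDI = params$fe * gaussian_signal(b, params$De) +
      params$fn * stick_powder_signal(b, params$Dn) +
      params$fs * soma_term() + params$fim,
    SMEX = ,
    SANDIX = ,
    eSANDIX = {
      fx <- params$fe + params$fn        # weight of the exchanging block
      rn <- 1 / params$tau_n
      Sx <- if (fx > 0)
        stick_exchange_powder(b, Delta, delta, params$Dn, params$De,
                              fn = params$fn / fx, rn = rn, quad = quad)
      else 0
      fx * Sx + params$fs * soma_term() +
        params$fn_imp * stick_powder_signal(b, params$Dn) + params$fim
    })
  signal_table(b, Delta, delta, S, provenance = "model")
}

#' Construct a powder signal table
#'
#' @param b,Delta,delta Encoding columns (ms/um^2 and ms).
#' @param S Powder-averaged signal as a fraction of S0.
#' @param sigma Optional noise level (fraction of S0).
#' @param provenance One of `"measured"`, `"synthetic"`, `"model"`.
#' @return A `"powder_signal"` data frame with unique `(b, Delta, delta)`
#'   keys, sorted by `Delta` then `b`.
#' @export
signal_table <- function(b, Delta, delta, S, sigma = NULL,
                         provenance = c("model", "synthetic", "measured")) {
  provenance <- match.arg(provenance)
  tab <- data.frame(b = b, Delta = Delta, delta = delta, S = S)
  if (!is.null(sigma)) tab$sigma <- sigma
  if (anyDuplicated(tab[c("b", "Delta", "delta")]))
    stop("duplicate (b, Delta, delta) keys in signal table")
  tab <- tab[order(tab$Delta, tab$b), , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, class = c("powder_signal", "data.frame"),
            provenance = provenance)
}

#' Read/write powder signal tables as delimited text
#'
#' Header columns `b,Delta,delta,S[,sigma]`; numeric values round-trip at 12
#' significant digits.
#'
#' @param file Path to the table.
#' @return For `read_signal_table`, a `"powder_signal"` data frame.
#' @export
read_signal_table <- function(file) {
  tab <- .read_delim_auto(file)
  need <- c("b", "Delta", "delta", "S")
  if (!all(need %in% names(tab)))
    stop("signal table must have columns b, Delta, delta, S")
  signal_table(tab$b, tab$Delta, tab$delta, tab$S,
               sigma = if ("sigma" %in% names(tab)) tab$sigma,
               provenance = "measured")
}

#' @rdname read_signal_table
#' @param tab A `"powder_signal"` data frame.
#' @export
write_signal_table <- function(tab, file) {
  keep <- intersect(c("b", "Delta", "delta", "S", "sigma"), names(tab))
  .write_delim(as.data.frame(tab)[keep], file)
  invisible(file)
}

#' Apparent power-law exponent of a signal curve
#'
#' Absolute slope of the ordinary least-squares line through
#' `(ln b, ln S)` over the window `b` in `[b_min, b_max]` (defaults 10 to
#' 100 ms/um^2), for a single `(Delta, delta)` combination.  A pure stick
#' gives 1/2; Gaussian compartments give larger apparent exponents.
#'
#' @param tab A `"powder_signal"` data frame restricted to one
#'   `(Delta, delta)`.
#' @param b_min,b_max Fitting window in ms/um^2.
#' @return The apparent exponent (dimensionless, positive).
#' @export
powerlaw_exponent <- function(tab, b_min = 10, b_max = 100) {
  if (length(unique(paste(tab$Delta, tab$delta))) > 1)
    stop("restrict the table to a single (Delta, delta) combination")
  sel <- tab$b >= b_min & tab$b <= b_max & tab$S > 0
  if (sum(sel) < 4) stop("need at least 4 points with b in the fitting window")
  fit <- lm(log(S) ~ log(b), data = tab[sel, ])
  abs(unname(coef(fit)[2]))
}

#' Classify the sign of the diffusion-time dependence at fixed b
#'
#' For every b-value shared by at least two diffusion times, compares the
#' signal across increasing `Delta`.  Differences within a relative
#' dead-band do not vote.  Exchange-dominated signals decrease with time;
#' structure-dominated (restricted, non-exchanging) signals increase.
#'
#' @param tab A `"powder_signal"` data frame spanning several `Delta` at
#'   shared b-values.
#' @param deadband Relative tolerance below which a difference is treated
#'   as flat (default 0.5%).
#' @param b_min Only b-values at or above this take part (default 0).
#' @return One of `"decreasing"`, `"increasing"`, `"mixed"` (mixed is also
#'   returned when every comparison is within the dead-band), with a
#'   `votes` attribute giving the per-b classification.
#' @export
time_dependence_sign <- function(tab, deadband = 0.005, b_min = 0) {
  bs <- unique(tab$b[tab$b >= b_min])
  votes <- vapply(bs, function(bb) {
    sub <- tab[tab$b == bb, , drop = FALSE]
    if (nrow(sub) < 2) return(NA_integer_)
    sub <- sub[order(sub$Delta), ]
    d <- diff(sub$S) / pmax(abs(sub$S[-nrow(sub)]), .Machine$double.eps)
    sig <- sign(d[abs(d) > deadband])
    if (length(sig) == 0) return(0L)
    if (all(sig < 0)) return(-1L)
    if (all(sig > 0)) return(1L)
    NA_integer_  # internally contradictory at this b
  }, integer(1))
  votes <- votes[!is.na(votes)]
  active <- votes[votes != 0L]
  out <- if (length(active) == 0) "mixed"
    else if (all(active < 0)) "decreasing"
    else if (all(active > 0)) "increasing"
    else "mixed"
  structure(out, votes = votes)
}

#' Powder diffusion-kurtosis summary at low b
#'
#' Least-squares cumulant fit `ln S = -b D + (1/6) b^2 D^2 K` to the subset
#' of the curve with `b <= b_max` (default 3 ms/um^2).  The fit is linear in
#' `(D, c2 = D^2 K / 6)`.
#'
#' @param tab A `"powder_signal"` data frame (one `(Delta, delta)`).
#' @param b_max Upper end of the fitting window, ms/um^2.
#' @return List with `D` (um^2/ms) and `K` (dimensionless).
#' @export
dki_powder_fit <- function(tab, b_max = 3) {
  sel <- tab$b <= b_max & tab$b > 0 & tab$S > 0
  if (sum(sel) < 3) stop("need at least 3 positive-b points with b <= b_max")
  b <- tab$b[sel]; y <- log(tab$S[sel])
  fit <- lm(y ~ 0 + b + I(b^2))
  D <- -unname(coef(fit)[1])
  c2 <- unname(coef(fit)[2])
  list(D = D, K = 6 * c2 / D^2)
}
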