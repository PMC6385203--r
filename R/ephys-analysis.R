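#' Stimulus protocol and current traces
#'
#' `stimulus_protocol()` describes one acid application: the acid window
#' (seconds, relative to trace start), conditioning and stimulation pH, and
#' the modulating-ligand concentration (0 when absent). `current_trace()`
#' pairs a uniformly sampled current recording with its protocol. Currents
#' are in microampere with the inward-negative sign convention of
#' two-electrode voltage clamp.
#'
#' @param acid_start,acid_end start/end of the acid application, s.
#' @param conditioning_pH pH of the conditioning solution (default 7.4).
#' @param acid_pH pH of the stimulation solution (default 5).
#' @param ligand_conc modulating peptide concentration, mol/L (default 0).
#' @param t time vector, s, uniformly sampled.
#' @param i current vector, uA, same length as `t`.
#' @param protocol a `stimulus_protocol`.
#' @return objects of class `stimulus_protocol` / `current_trace`.
#' @export
stimulus_protocol <- function(acid_start, acid_end, conditioning_pH = 7.4,
                              acid_pH = 5, ligand_conc = 0) {
  if (acid_end <= acid_start) stop("acid_end must be after acid_start")
  structure(list(acid_start = acid_start, acid_end = acid_end,
                 conditioning_pH = conditioning_pH, acid_pH = acid_pH,
                 ligand_conc = ligand_conc), class = "stimulus_protocol")
}

#' @rdname stimulus_protocol
#' @export
current_trace <- function(t, i, protocol) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  if (length(t) != length(i)) stop("t and i must have equal length")
  if (length(t) < 2L) stop("trace too short")
  dt <- diff(t)
  if (any(dt <= 0) || diff(range(dt)) > 1e-6 * mean(dt))
    stop("trace must be uniformly sampled with dt > 0")
  if (protocol$acid_start < t[1] || protocol$acid_end > t[length(t)])
    stop("protocol acid window exceeds trace length")
  structure(list(t = as.numeric(t), i = as.numeric(i), protocol = protocol),
            class = "current_trace")
}

#' Peak and sustained current metrics of a trace
#'
#' Baseline is the mean current over the `baseline_window` seconds preceding
#' the acid application; the peak is the maximum baseline-subtracted
#' absolute amplitude within the acid window; the sustained current is the
#' mean baseline-subtracted absolute amplitude over the last
#' `sustained_window` seconds of the acid application (2 s by default). The
#' modulation readout is the ratio I_sust/I_peak, reported positive
#' regardless of the inward-negative plotting convention.
#'
#' @param trace a [current_trace] whose acid window is at least
#'   `sustained_window` long.
#' @param baseline_window s before acid onset used for the baseline (2).
#' @param sustained_window s at the end of the acid window (2).
#' @param noise_floor minimal usable peak amplitude, uA; traces whose peak is
#'   below it are flagged `usable = FALSE` (default 0 disables the check).
#' @return list of class `trace_metrics`: `baseline`, `i_peak`, `i_sust`
#'   (both uA, magnitudes), `ratio`, `usable`.
#' @export
trace_metrics <- function(trace, baseline_window = 2, sustained_window = 2,
                          noise_floor = 0) {
  stopifnot(inherits(trace, "current_trace"))
  p <- trace$protocol
  if (p$acid_end - p$acid_start < sustained_window)
    stop("acid window shorter than the sustained-current window")
  t <- trace$t; i <- trace$i
  base_sel <- t >= p$acid_start - baseline_window & t < p$acid_start
  if (!any(base_sel)) stop("no samples in the baseline window")
  baseline <- mean(i[base_sel])
  acid_sel <- t >= p$acid_start & t <= p$acid_end
  dev <- abs(i[acid_sel] - baseline)
  i_peak <- max(dev)
  sust_sel <- t >= p$acid_end - sustained_window & t <= p$acid_end
  i_sust <- mean(abs(i[sust_sel] - baseline))
  usable <- i_peak >= noise_floor
  structure(list(baseline = baseline, i_peak = i_peak, i_sust = i_sust,
                 ratio = if (i_peak > 0) i_sust / i_peak else NA_real_,
                 usable = usable),
            class = "trace_metrics")
}

#' Steady-state desensitization Hill curve
#'
#' The SSD pH dependence follows
#' `I = Imax * (1 - 1 / (1 + (10^-pHD50 / 10^-pH)^nH))`:
#' at conditioning pH well above pHD50 the current is maximal, at pH = pHD50
#' it is exactly Imax/2, and acidic conditioning desensitizes the channel
#' completely.
#'
#' @param pH conditioning pH values.
#' @param pHD50 midpoint of desensitization (pH units).
#' @param nH Hill coefficient (> 0).
#' @param Imax maximal (normalized) current.
#' @return predicted current at each `pH`.
#' @export
hill_ssd <- function(pH, pHD50, nH, Imax = 1) {
  Imax * (1 - 1 / (1 + 10^(nH * (pH - pHD50))))
}

#' Fit the steady-state desensitization curve
#'
#' Levenberg-Marquardt least squares of [hill_ssd] with three deterministic
#' initializations (data-driven midpoint and +/- 0.5 pH units) to avoid
#' local minima; the best residual sum of squares wins. Currents may be raw
#' amplitudes; `Imax` is fitted, so normalization to the fitted maximum is
#' implicit.
#'
#' @param cond_pH conditioning pH values (>= 4 distinct, spanning the
#'   transition).
#' @param i_norm current amplitudes at each pH.
#' @return list of class `ssd_fit`: `pHD50`, `nH`, `Imax`, `covariance`,
#'   `rss`, `fitted` (function of pH), `data`.
#' @export
fit_ssd <- function(cond_pH, i_norm) {
  stopifnot(length(cond_pH) == length(i_norm))
  if (length(unique(cond_pH)) < 4L)
    stop("need at least 4 distinct conditioning pH values")
  if (sd(i_norm) == 0) stop("degenerate data: all currents equal")
  df <- data.frame(pH = cond_pH, I = i_norm)
  imax0 <- max(i_norm)
  mid0 <- cond_pH[which.min(abs(i_norm - imax0 / 2))]
  fits <- list()
  for (m0 in mid0 + c(0, -0.5, 0.5)) {
    f <- tryCatch(
      minpack.lm::nlsLM(I ~ hill_ssd(pH, pHD50, nH, Imax), data = df,
                        start = list(pHD50 = m0, nH = 3, Imax = imax0),
                        lower = c(min(cond_pH) - 2, 1e-3, 1e-12),
                        upper = c(max(cond_pH) + 2, 50, Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(f)) fits[[length(fits) + 1L]] <- f
  }
  if (length(fits) == 0L)
    stop("SSD fit did not converge from any initialization; ",
         "check that the pH range spans the transition")
  rss <- vapply(fits, function(f) sum(residuals(f)^2), numeric(1))
  f <- fits[[which.min(rss)]]
  cf <- coef(f)
  structure(list(pHD50 = unname(cf["pHD50"]), nH = unname(cf["nH"]),
                 Imax = unname(cf["Imax"]),
                 covariance = tryCatch(vcov(f), error = function(e) NULL),
                 rss = min(rss),
                 fitted = function(pH) hill_ssd(pH, cf["pHD50"], cf["nH"],
                                                cf["Imax"]),
                 data = df),
            class = "ssd_fit")
}

#' Fit a concentration-response (Hill-Langmuir) curve
#'
#' Fits `r(c) = r_0 + (r_max - r_0) * c^h / (EC50^h + c^h)` to sustained/peak
#' current ratios measured at several modulator concentrations. EC50 is
#' parameterized on the log10 scale for stability; initializations at the
#' apparent midpoint and +/- 0.5 log-units.
#'
#' @param conc concentrations, mol/L (>= 4, bracketing the apparent EC50;
#'   `conc = 0` points anchor `r_0`).
#' @param ratios response at each concentration.
#' @return list of class `dose_response_fit`: `EC50` (mol/L), `hill`,
#'   `r_max`, `r_0`, `covariance`, `rss`, `fitted`, `data`.
#' @export
fit_dose_response <- function(conc, ratios) {
  stopifnot(length(conc) == length(ratios))
  if (length(unique(conc)) < 4L) stop("need at least 4 concentrations")
  if (all(ratios == 0)) stop("all responses are zero")
  df <- data.frame(c = conc, r = ratios)
  drc <- function(c, lec50, h, rmax, r0) {
    ec <- 10^lec50
    r0 + (rmax - r0) * ifelse(c > 0, c^h / (ec^h + c^h), 0)
  }
  r0_0 <- min(ratios); rmax_0 <- max(ratios)
  half <- r0_0 + (rmax_0 - r0_0) / 2
  pos <- conc > 0
  lec0 <- log10(conc[pos][which.min(abs(ratios[pos] - half))])
  fits <- list()
  for (l0 in lec0 + c(0, -0.5, 0.5)) {
    f <- tryCatch(
      minpack.lm::nlsLM(r ~ drc(c, lec50, h, rmax, r0), data = df,
                        start = list(lec50 = l0, h = 1, rmax = rmax_0,
                                     r0 = r0_0),
                        lower = c(log10(min(conc[pos])) - 4, 0.05, -Inf, -Inf),
                        upper = c(log10(max(conc)) + 4, 20, Inf, Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(f)) fits[[length(fits) + 1L]] <- f
  }
  if (length(fits) == 0L) stop("dose-response fit did not converge")
  rss <- vapply(fits, function(f) sum(residuals(f)^2), numeric(1))
  f <- fits[[which.min(rss)]]
  cf <- coef(f)
  structure(list(EC50 = unname(10^cf["lec50"]), hill = unname(cf["h"]),
                 r_max = unname(cf["rmax"]), r_0 = unname(cf["r0"]),
                 covariance = tryCatch(vcov(f), error = function(e) NULL),
                 rss = min(rss),
                 fitted = function(c) drc(c, cf["lec50"], cf["h"],
                                          cf["rmax"], cf["r0"]),
                 data = df),
            class = "dose_response_fit")
}

#' Fit mono-exponential association/dissociation kinetics
#'
#' Fits `y = A * exp(-rate * t) + offset` (decay, e.g. washout of the
#' sustained current giving k_off) or `y = A * (1 - exp(-rate * t)) + offset`
#' (rise, e.g. appearance of the sustained current during pre-application).
#' For a rise measured at ligand concentration `[L]`, the association rate
#' constant is derived as `k_on = rate / [L]` (pseudo-first-order; the
#' two-state variant `k_on = (rate - k_off) / [L]` is available via
#' `kon_model = "with_koff"`).
#'
#' @param t time points, s (>= 4).
#' @param y observed values.
#' @param mode `"decay"` or `"rise"`.
#' @param ligand_conc mol/L; when given for a rise, `k_on` is computed.
#' @param kon_model `"pseudo_first_order"` (default) or `"with_koff"`.
#' @param k_off s^-1, required for `kon_model = "with_koff"`.
#' @return list of class `kinetic_fit`: `rate` (s^-1), `k_on` (s^-1 M^-1 or
#'   `NA`), `amplitude`, `offset`, `covariance`, `rss`, `fitted`, `data`.
#' @export
fit_exponential_kinetics <- function(t, y, mode = c("decay", "rise"),
                                     ligand_conc = NULL,
                                     kon_model = c("pseudo_first_order",
                                                   "with_koff"),
                                     k_off = NULL) {
  mode <- match.arg(mode)
  kon_model <- match.arg(kon_model)
  stopifnot(length(t) == length(y))
  if (length(t) < 4L) stop("need at least 4 time points")
  if (sd(y) == 0) stop("constant y: rate is unidentifiable")
  df <- data.frame(t = t, y = y)
  fml <- if (mode == "decay") y ~ A * exp(-rate * t) + off
  else y ~ A * (1 - exp(-rate * t)) + off
  span <- diff(range(t))
  rate0 <- 2 / span
  A0 <- if (mode == "decay") y[which.min(t)] - y[which.max(t)]
  else y[which.max(t)] - y[which.min(t)]
  off0 <- if (mode == "decay") y[which.max(t)] else y[which.min(t)]
  fits <- list()
  for (r0 in rate0 * 10^c(-0.75, 0, 0.75)) {
    f <- tryCatch(
      minpack.lm::nlsLM(fml, data = df,
                        start = list(A = A0, rate = r0, off = off0),
                        lower = c(-Inf, 1e-9, -Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(f)) fits[[length(fits) + 1L]] <- f
  }
  if (length(fits) == 0L) stop("kinetic fit did not converge")
  rss <- vapply(fits, function(f) sum(residuals(f)^2), numeric(1))
  f <- fits[[which.min(rss)]]
  cf <- coef(f)
  rate <- unname(cf["rate"])
  if (rate <= 0) stop("fitted rate is not positive")
  k_on <- NA_real_
  if (!is.null(ligand_conc) && mode == "rise") {
    if (ligand_conc <= 0) stop("ligand_conc must be > 0 to derive k_on")
    k_on <- if (kon_model == "pseudo_first_order") rate / ligand_conc
    else {
      if (is.null(k_off)) stop("k_off required for kon_model = 'with_koff'")
      (rate - k_off) / ligand_conc
    }
  }
  pred <- function(tt) {
    if (mode == "decay") cf["A"] * exp(-rate * tt) + cf["off"]
    else cf["A"] * (1 - exp(-rate * tt)) + cf["off"]
  }
  structure(list(rate = rate, k_on = k_on, amplitude = unname(cf["A"]),
                 offset = unname(cf["off"]),
                 covariance = tryCatch(vcov(f), error = function(e) NULL),
                 rss = min(rss), fitted = pred, data = df, mode = mode),
            class = "kinetic_fit")
}

#' Classify wild-type vs mutant modulation effects
#'
#' Reproduces the semantics of a mutation-summary table: for each mutant,
#' the peptide-induced fold change of the sustained/peak ratio, the
#' peptide-induced pHD50 shift, and the Hill-coefficient ratio of the SSD
#' curve are compared against wild type, and each parameter is annotated
#' `"<"`, `"="` or `">"`: different from WT in the stated direction at level
#' `alpha`, or not significantly different. Mutants are compared to WT by
#' Welch's t-test with Holm correction across mutants within each parameter
#' (a pairwise approximation to a many-to-one post-hoc test).
#'
#' Replicate tables have one row per cell and columns `isust_ctrl`,
#' `isust_frrfa` and optionally `phd50_ctrl`, `phd50_frrfa`, `nh_ctrl`,
#' `nh_frrfa`. Per cell, the I_sust effect is the fold change
#' `isust_frrfa / isust_ctrl`, the SSD shift is
#' `phd50_frrfa - phd50_ctrl` and the steepness change `nh_frrfa / nh_ctrl`.
#'
#' @param wt replicate table for wild type (>= 3 rows).
#' @param muts named list of mutant replicate tables (a single data.frame is
#'   treated as one mutant named `"mutant"`).
#' @param alpha significance level (0.05).
#' @return data.frame of class `modulation_comparison`, one row per mutant:
#'   fold changes, per-genotype deltas/ratios, Holm-adjusted p values and the
#'   three symbols `sym_isust`, `sym_dphd50`, `sym_nh`.
#' @export
compare_modulation <- function(wt, muts, alpha = 0.05) {
  if (is.data.frame(muts)) muts <- list(mutant = muts)
  if (is.null(names(muts)) || any(!nzchar(names(muts))))
    stop("`muts` must be a named list of replicate tables")
  check_tab <- function(x, who) {
    if (nrow(x) < 3L) stop(who, ": need at least 3 replicates")
    if (!all(c("isust_ctrl", "isust_frrfa") %in% names(x)))
      stop(who, ": missing isust_ctrl/isust_frrfa columns")
  }
  check_tab(wt, "wt")
  for (nm in names(muts)) check_tab(muts[[nm]], nm)

  derive <- function(x) {
    out <- list(fold = x$isust_frrfa / x$isust_ctrl)
    out$dphd50 <- if (all(c("phd50_ctrl", "phd50_frrfa") %in% names(x)))
      x$phd50_frrfa - x$phd50_ctrl else NULL
    out$nhr <- if (all(c("nh_ctrl", "nh_frrfa") %in% names(x)))
      x$nh_frrfa / x$nh_ctrl else NULL
    out
  }
  w <- derive(wt)
  res <- lapply(names(muts), function(nm) {
    m <- derive(muts[[nm]])
    cmp <- function(a, b) {
      if (is.null(a) || is.null(b)) return(list(p = NA_real_, d = NA_real_))
      list(p = t.test(b, a)$p.value, d = mean(b) - mean(a))
    }
    ci <- cmp(w$fold, m$fold)
    cp <- cmp(w$dphd50, m$dphd50)
    cn <- cmp(w$nhr, m$nhr)
    data.frame(genotype = nm,
               fold_change_wt = mean(w$fold), fold_change_mut = mean(m$fold),
               fold_change_ratio = mean(m$fold) / mean(w$fold),
               delta_phd50_wt = if (is.null(w$dphd50)) NA_real_ else
                 mean(w$dphd50),
               delta_phd50_mut = if (is.null(m$dphd50)) NA_real_ else
                 mean(m$dphd50),
               nh_ratio_wt = if (is.null(w$nhr)) NA_real_ else mean(w$nhr),
               nh_ratio_mut = if (is.null(m$nhr)) NA_real_ else mean(m$nhr),
               p_isust = ci$p, p_dphd50 = cp$p, p_nh = cn$p,
               d_isust = ci$d, d_dphd50 = cp$d, d_nh = cn$d,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  # Holm correction across mutants, within each parameter
  for (col in c("p_isust", "p_dphd50", "p_nh")) {
    ok <- !is.na(res[[col]])
    res[[col]][ok] <- p.adjust(res[[col]][ok], method = "holm")
  }
  symbol <- function(p, d, flip = FALSE) {
    ifelse(is.na(p) | p >= alpha, "=",
           ifelse(xor(d < 0, flip), "<", ">"))
  }
  res$sym_isust <- symbol(res$p_isust, res$d_isust)
  # a *smaller* (more negative) pHD50 shift in the mutant means less shift
  # only when WT's shift is negative; the table's convention is
  # "<" = smaller magnitude of the FRRFa-induced change than WT
  res$sym_dphd50 <- symbol(res$p_dphd50,
                           abs(res$delta_phd50_mut) - abs(res$delta_phd50_wt))
  # nH ratio ~0.5 in WT; a higher ratio in the mutant = less change = ">"
  res$sym_nh <- symbol(res$p_nh, res$d_nh)
  res[, c("d_isust", "d_dphd50", "d_nh")] <- NULL
  rownames(res) <- NULL
  class(res) <- c("modulation_comparison", "data.frame")
  res
}

#' Read a current trace from CSV + protocol JSON
#'
#' The CSV must have columns `t_s` and `i_uA`; the protocol JSON holds the
#' fields of [stimulus_protocol].
#'
#' @param csv_path trace CSV path.
#' @param protocol_path protocol JSON path.
#' @return a [current_trace].
#' @export
read_trace_csv <- function(csv_path, protocol_path) {
  df <- read.csv(csv_path)
  if (!all(c("t_s", "i_uA") %in% names(df)))
    stop("trace CSV ", csv_path, " must have columns t_s, i_uA")
  pj <- jsonlite::read_json(protocol_path, simplifyVector = TRUE)
  prot <- stimulus_protocol(pj$acid_start, pj$acid_end,
                            conditioning_pH = pj$conditioning_pH %||% 7.4,
                            acid_pH = pj$acid_pH %||% 5,
                            ligand_conc = pj$ligand_conc %||% 0)
  current_trace(df$t_s, df$i_uA, prot)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a current trace to CSV + protocol JSON
#'
#' @param trace a [current_trace].
#' @param csv_path,protocol_path output paths.
#' @return `csv_path`, invisibly.
#' @export
write_trace_csv <- function(trace, csv_path, protocol_path) {
  write.csv(data.frame(t_s = trace$t, i_uA = trace$i), csv_path,
            row.names = FALSE)
  jsonlite::write_json(unclass(trace$protocol), protocol_path,
                       auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}
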