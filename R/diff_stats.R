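#' Differential abundance test for aggregated link species
#'
#' For each link, a pooled-variance (homoscedastic) two-sample t statistic
#' is computed on normalized intensities, with the one-tailed p-value taken
#' in the direction of the observed mean difference — the procedure that
#' yields both increasing and decreasing calls from one test. Fold change
#' is mean(treated)/mean(control). A link is significant when p < `alpha`
#' AND fold change > `fc_threshold` or < 1/`fc_threshold` (both strict).
#'
#' Degenerate cases are reported, not hidden: zero pooled variance with
#' unequal means gives p = 0 with `degenerate_variance = TRUE`; a zero
#' control mean gives `fold_change = Inf` with `zero_control_mean = TRUE`.
#'
#' @param quant `xlms_quant` from [aggregate_links()], or a plain numeric
#'   matrix links x samples (then `samples` must be supplied).
#' @param control,treated Condition labels to compare.
#' @param alpha Significance level on the one-tailed p-value (default 0.05).
#' @param fc_threshold Strict fold-change threshold (default 2).
#' @param log_scale If `TRUE`, the t-test runs on log2 intensities
#'   (fold change is still reported on the natural scale). Off by default.
#' @param tail `"auto"` (default) takes the one-tailed p in the direction
#'   of each link's observed mean difference — the screening procedure
#'   that yields both increasing and decreasing calls from one test.
#'   `"increase"`/`"decrease"` fix the alternative for every link, giving
#'   the test its nominal one-sided size (with `"auto"`, a null link
#'   crosses p < alpha in either direction, so the null rate is 2*alpha).
#' @param adjust P-value adjustment method passed to [stats::p.adjust()];
#'   `"none"` (default) reports raw p-values as-is; `"BH"` adds a
#'   `p_adjusted` column (significance still uses the raw p, for parity
#'   with the uncorrected workflow, unless `use_adjusted = TRUE`).
#' @param use_adjusted Gate significance on the adjusted p-value.
#' @param samples `data.frame(condition, replicate)` when `quant` is a bare
#'   matrix.
#' @return `data.frame` (class `xlms_diff`), one row per link: `link`,
#'   `link_kind`, `fold_change`, `direction` (increase/decrease/none),
#'   `p_value`, `significant`, `n_control`, `n_treated`,
#'   `mean_control`, `mean_treated`, flags.
#' @export
differential_test <- function(quant, control, treated, alpha = 0.05,
                              fc_threshold = 2, log_scale = FALSE,
                              tail = c("auto", "increase", "decrease"),
                              adjust = "none", use_adjusted = FALSE,
                              samples = NULL) {
  tail <- match.arg(tail)
  if (inherits(quant, "xlms_quant")) {
    m <- quant$intensity
    samples <- quant$samples
    kinds <- quant$links$link_kind
  } else {
    m <- as.matrix(quant)
    if (is.null(samples)) stop("samples data.frame required for a bare matrix")
    kinds <- rep(NA_character_, nrow(m))
  }
  stopifnot(all(c(control, treated) %in% samples$condition))
  mc <- m[, samples$condition == control, drop = FALSE]
  mt <- m[, samples$condition == treated, drop = FALSE]

  n_c <- rowSums(!is.na(mc))
  n_t <- rowSums(!is.na(mt))
  if (any(n_c == 0 | n_t == 0)) {
    bad <- rownames(m)[n_c == 0 | n_t == 0]
    stop("link(s) with an all-missing condition: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  if (any(n_c < 2 | n_t < 2)) {
    warning("link(s) with <2 replicates in a condition; t-test undefined there")
  }

  mean_c <- rowMeans(mc, na.rm = TRUE)
  mean_t <- rowMeans(mt, na.rm = TRUE)
  fc <- mean_t / mean_c
  zero_ctrl <- mean_c == 0 & mean_t > 0
  fc[zero_ctrl] <- Inf

  xc <- mc; xt <- mt
  if (log_scale) { xc <- log2(mc); xt <- log2(mt) }
  tm_c <- rowMeans(xc, na.rm = TRUE)
  tm_t <- rowMeans(xt, na.rm = TRUE)
  ss <- function(x, mu) rowSums((x - mu)^2, na.rm = TRUE)
  df <- n_c + n_t - 2
  sp2 <- (ss(xc, tm_c) + ss(xt, tm_t)) / pmax(df, 1)
  se <- sqrt(sp2 * (1 / n_c + 1 / n_t))
  delta <- tm_t - tm_c
  tstat <- delta / se

  p <- switch(tail,
    auto = stats::pt(-abs(tstat), df),
    increase = stats::pt(tstat, df, lower.tail = FALSE),
    decrease = stats::pt(tstat, df))
  degenerate <- se == 0
  if (any(degenerate)) {
    dd <- delta[degenerate]
    ts <- switch(tail,
                 auto = sign(dd),
                 increase = rep(1, length(dd)),
                 decrease = rep(-1, length(dd)))
    p[degenerate] <- ifelse(dd != 0 & sign(dd) == ts, 0, 1)
  }
  p[df < 1] <- NA_real_

  direction <- ifelse(fc > 1, "increase", ifelse(fc < 1, "decrease", "none"))
  p_adj <- if (adjust != "none") stats::p.adjust(p, method = adjust) else NULL
  p_gate <- if (use_adjusted && !is.null(p_adj)) p_adj else p
  significant <- !is.na(p_gate) & p_gate < alpha &
    (fc > fc_threshold | fc < 1 / fc_threshold)

  out <- data.frame(
    link = rownames(m),
    link_kind = kinds,
    fold_change = unname(fc),
    direction = unname(direction),
    p_value = unname(p),
    significant = unname(significant),
    n_control = unname(n_c),
    n_treated = unname(n_t),
    mean_control = unname(mean_c),
    mean_treated = unname(mean_t),
    degenerate_variance = unname(degenerate),
    zero_control_mean = unname(zero_ctrl),
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (!is.null(p_adj)) out$p_adjusted <- unname(p_adj)
  class(out) <- c("xlms_diff", "data.frame")
  attr(out, "control") <- control
  attr(out, "treated") <- treated
  out
}

#' Census of links changed at least twofold
#'
#' Counts link species whose fold change is >= `min_fc` or <= 1/`min_fc`
#' between the two conditions, by link kind. Note the census threshold is
#' inclusive ("at least twofold"), distinct from the strict threshold used
#' for significance calls.
#'
#' @param results `xlms_diff` from [differential_test()].
#' @param min_fc Inclusive fold-change threshold (default 2).
#' @return Named integer vector: counts for `interpeptide`, `intrapeptide`,
#'   `monolink`, and `total`.
#' @export
count_changed_links <- function(results, min_fc = 2) {
  changed <- results$fold_change >= min_fc | results$fold_change <= 1 / min_fc
  kinds <- c("interpeptide", "intrapeptide", "monolink")
  counts <- vapply(kinds, function(k) {
    sum(changed & results$link_kind == k, na.rm = TRUE)
  }, integer(1))
  c(counts, total = sum(changed, na.rm = TRUE))
}

#' Compare interacting-heads-motif head fractions between conditions
#'
#' Negative-stain head counting: each image contributes one IHM percentage
#' `100 * n_ihm / (n_open + n_ihm)`; images with fewer than `min_particles`
#' total particles are excluded (so each retained image estimates its
#' fraction with adequate power), and the two conditions are compared with
#' a two-tailed unpaired Student's (equal-variance) t-test on the per-image
#' percentages.
#'
#' @param counts `data.frame` with columns `condition`, `n_open`, `n_ihm`.
#' @param condition_a,condition_b The two condition labels to compare.
#' @param min_particles Per-image inclusion threshold (default 250).
#' @return List: `p_value`, `fractions` (per-image percentages with
#'   condition and inclusion flag), `excluded` (rows dropped),
#'   `mean_a`, `mean_b`.
#' @export
headcount_compare <- function(counts, condition_a, condition_b,
                              min_particles = 250) {
  stopifnot(all(c("condition", "n_open", "n_ihm") %in% names(counts)))
  counts$total <- counts$n_open + counts$n_ihm
  counts$included <- counts$total >= min_particles
  counts$ihm_pct <- 100 * counts$n_ihm / counts$total
  keep <- counts[counts$included, ]
  a <- keep$ihm_pct[keep$condition == condition_a]
  b <- keep$ihm_pct[keep$condition == condition_b]
  if (length(a) < 2 || length(b) < 2) {
    stop("fewer than 2 included images in a condition (",
         condition_a, ": ", length(a), ", ", condition_b, ": ", length(b), ")")
  }
  p <- if (stats::sd(c(a - mean(a), b - mean(b))) == 0) {
    if (mean(a) == mean(b)) 1 else 0
  } else {
    stats::t.test(a, b, var.equal = TRUE)$p.value
  }
  list(p_value = p,
       fractions = counts[, c("condition", "ihm_pct", "included")],
       excluded = counts[!counts$included, , drop = FALSE],
       mean_a = mean(a), mean_b = mean(b))
}
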