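#' Mann-Whitney U test with exact small-sample p
#'
#' U is computed from midranks (ties shared). When both samples are smaller
#' than `exact_below` and tie-free, the two-sided p comes from the exact
#' distribution of U under permutation of group labels; otherwise from the
#' normal approximation with tie correction and continuity correction.
#'
#' @param x,y numeric samples.
#' @param exact_below exact-enumeration size cutoff (default 12).
#' @return list with `U` (for `x`), `p` (two-sided) and `method`.
#' @export
mann_whitney <- function(x, y, exact_below = 12L) {
  x <- as.numeric(x); y <- as.numeric(y)
  n1 <- length(x); n2 <- length(y)
  if (!n1 || !n2) stop("both samples must be nonempty", call. = FALSE)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(x, y))
  has_ties <- any(ties > 1)
  if (length(ties) == 1L)   # all values identical across both samples
    return(list(U = U, p = 1, method = "degenerate"))
  if (!has_ties && n1 < exact_below && n2 < exact_below) {
    # exact two-sided p from the null distribution of U
    p <- 2 * min(stats::pwilcox(U, n1, n2),
                 1 - stats::pwilcox(U - 1, n1, n2))
    return(list(U = U, p = min(1, p), method = "exact"))
  }
  N <- n1 + n2
  mu <- n1 * n2 / 2
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma <- sqrt(n1 * n2 / 12 * (N + 1 - tie_term))
  if (sigma == 0) return(list(U = U, p = 1, method = "degenerate"))
  z <- (U - mu - sign(U - mu) * 0.5) / sigma
  list(U = U, p = min(1, 2 * stats::pnorm(-abs(z))), method = "normal")
}

#' Spearman rank correlation with t-approximation p
#'
#' Midrank-based rho; p from the t approximation with n - 2 degrees of
#' freedom. Zero variance in either input yields `rho = NA` with
#' `defined = FALSE`.
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @return list with `rho`, `p`, `n`, `defined`.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("spearman needs n >= 3", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n, defined = FALSE))
  rho <- stats::cor(rx, ry)
  tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  list(rho = rho, p = p, n = n, defined = TRUE)
}

#' Classic one-way fixed-effects ANOVA
#'
#' @param groups list of numeric samples (>= 2 groups, each n >= 2).
#' @return list with `F`, `p`, `df`.
#' @export
anova_oneway <- function(groups) {
  if (length(groups) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (any(lengths(groups) < 2L)) stop("each group needs n >= 2", call. = FALSE)
  vals <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(seq_along(groups), lengths(groups)))
  if (all(tapply(vals, fac, stats::sd) == 0)) {
    means <- tapply(vals, fac, mean)
    if (stats::sd(means) == 0) return(list(F = 0, p = 1, df = NULL,
                                           degenerate = TRUE))
    return(list(F = Inf, p = 0, df = NULL, degenerate = TRUE))
  }
  fit <- stats::oneway.test(vals ~ fac, var.equal = TRUE)
  list(F = unname(fit$statistic), p = unname(fit$p.value),
       df = unname(fit$parameter), degenerate = FALSE)
}

#' Node-wise correlation of enhancement ratio with hemodynamic indices
#'
#' Per-case Spearman correlation of ER against TAWSS, OSI, GON and RRT over
#' all vertices of the aneurysm segment, with a correlation-strength label
#' (`"moderate"` when `|rho| > 0.3`, else `"weak"`) and a significance flag
#' at p < 0.001. P-values are reported uncorrected (a Bonferroni option is
#' available).
#'
#' @param er per-vertex enhancement ratio.
#' @param maps named list of per-vertex hemodynamic maps (TAWSS, OSI, GON,
#'   RRT).
#' @param segment_mask logical vertex mask of the aneurysm segment.
#' @param bonferroni apply a 4-test Bonferroni correction (default FALSE).
#' @return data.frame with one row per index: `index`, `rho`, `p`,
#'   `strength`, `significant`, `defined`.
#' @export
node_correlations <- function(er, maps, segment_mask = NULL,
                              bonferroni = FALSE) {
  idx_names <- intersect(c("TAWSS", "OSI", "GON", "RRT"), names(maps))
  if (is.null(segment_mask)) segment_mask <- rep(TRUE, length(er))
  do.call(rbind, lapply(idx_names, function(nm) {
    m <- maps[[nm]][segment_mask]
    e <- er[segment_mask]
    fin <- is.finite(m) & is.finite(e)
    sp <- if (sum(fin) >= 3 && stats::sd(e[fin]) > 0 && stats::sd(m[fin]) > 0)
      spearman(e[fin], m[fin]) else
        list(rho = NA_real_, p = NA_real_, n = sum(fin), defined = FALSE)
    p_adj <- if (bonferroni && sp$defined) min(1, sp$p * length(idx_names))
    else sp$p
    data.frame(index = nm, rho = sp$rho, p = p_adj,
               strength = if (sp$defined && abs(sp$rho) > 0.3) "moderate"
               else "weak",
               significant = isTRUE(sp$defined && p_adj < 0.001),
               defined = sp$defined, stringsAsFactors = FALSE)
  }))
}

#' Cohort-level report tables
#'
#' From a per-case cohort table, emits the four result tables of the
#' analysis: (i) per-type mean +/- SD with Shapiro-Wilk normality and
#' one-way ANOVA p per variable; (ii) pooled per-case region means
#' (enhanced vs non-enhanced) with a Mann-Whitney p per index, plus a
#' paired Wilcoxon alternative; (iii) the per-case node-wise Spearman rho
#' grid; (iv) cohort Spearman of enhancement area against D_max and L_max.
#'
#' @param cohort_table data.frame with one row per case: `case_id`,
#'   `ifa_type`, the morphology/enhancement columns, per-region index means
#'   (`<index>_enh`, `<index>_non`), and per-case `rho_<index>` columns.
#' @param out_dir optional directory; when given, the four tables are
#'   written as `cohort_table1.csv`, `region_compare.csv`,
#'   `node_correlations.csv`, `size_correlation.csv`.
#' @param provenance optional character scalar written as a `# ...` header
#'   comment in each CSV.
#' @return named list of the four data.frames (invisibly when writing).
#' @export
cohort_report <- function(cohort_table, out_dir = NULL, provenance = NULL) {
  ct <- cohort_table
  types <- c("fusiform", "dolichoectatic", "transitional")
  num_vars <- c("d_max", "l_max", "kappa_max", "kappa_mean", "tau_max",
                "tau_mean", "cr_max", "enhancement_area",
                "proportion_enhanced",
                "TAWSS_max", "TAWSS_mean", "OSI_max", "OSI_mean",
                "GON_max", "GON_mean", "RRT_max", "RRT_mean")
  num_vars <- intersect(num_vars, names(ct))
  small_groups <- FALSE
  table1 <- do.call(rbind, lapply(num_vars, function(v) {
    groups <- lapply(types, function(ty) ct[[v]][ct$ifa_type == ty])
    an <- if (any(lengths(groups) < 2L)) {
      small_groups <<- TRUE
      list(p = NA_real_)
    } else anova_oneway(groups)
    sw_p <- tryCatch(stats::shapiro.test(ct[[v]])$p.value,
                     error = function(e) NA_real_)
    stats_row <- data.frame(variable = v,
                            fusiform_mean = mean(groups[[1]]),
                            fusiform_sd = stats::sd(groups[[1]]),
                            dolichoectatic_mean = mean(groups[[2]]),
                            dolichoectatic_sd = stats::sd(groups[[2]]),
                            transitional_mean = mean(groups[[3]]),
                            transitional_sd = stats::sd(groups[[3]]),
                            shapiro_p = sw_p,
                            anova_p = an$p, stringsAsFactors = FALSE)
    stats_row
  }))
  if (small_groups)
    warning("fewer than 2 cases in some type: ANOVA p left NA")

  # TAWSS_norm (parent-normalized) is the cross-patient comparable TAWSS;
  # the raw Pa means are reported alongside
  idx <- intersect(c("TAWSS", "TAWSS_norm", "OSI", "GON", "RRT"),
                   sub("_enh$", "", grep("_enh$", names(ct), value = TRUE)))
  region <- do.call(rbind, lapply(idx, function(nm) {
    enh <- ct[[paste0(nm, "_enh")]]
    non <- ct[[paste0(nm, "_non")]]
    keep <- is.finite(enh) & is.finite(non)
    mw <- mann_whitney(enh[keep], non[keep])
    wil <- stats::wilcox.test(enh[keep], non[keep], paired = TRUE,
                              exact = FALSE)
    data.frame(index = nm, enhanced_mean = mean(enh[keep]),
               nonenhanced_mean = mean(non[keep]), n_cases = sum(keep),
               mann_whitney_U = mw$U, mann_whitney_p = mw$p,
               paired_wilcoxon_p = wil$p.value, stringsAsFactors = FALSE)
  }))

  rho_cols <- paste0("rho_", idx)
  nodecor <- ct[, c("case_id", "ifa_type",
                    intersect(rho_cols, names(ct))), drop = FALSE]

  size <- do.call(rbind, lapply(c("d_max", "l_max"), function(v) {
    sp <- spearman(ct$enhancement_area, ct[[v]])
    data.frame(size_variable = v, rho = sp$rho, p = sp$p, n = sp$n,
               stringsAsFactors = FALSE)
  }))

  out <- list(cohort_table1 = table1, region_compare = region,
              node_correlations = nodecor, size_correlation = size)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(out)) {
      path <- file.path(out_dir, paste0(nm, ".csv"))
      con <- file(path, "w")
      if (!is.null(provenance)) writeLines(paste("#", provenance), con)
      utils::write.csv(out[[nm]], con, row.names = FALSE)
      close(con)
    }
    return(invisible(out))
  }
  out
}
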