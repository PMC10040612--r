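test_that("Mann-Whitney: exact enumeration fixture and degenerate cases", {
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p, 0.1)         # 2/20 arrangements as extreme
  expect_equal(res$method, "exact")

  same <- mann_whitney(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$p, 1)

  # against the reference implementation on a tie-free sample
  set.seed(1)
  x <- rnorm(8); y <- rnorm(9) + 0.5
  ours <- mann_whitney(x, y)
  ref <- wilcox.test(x, y, exact = TRUE)
  expect_equal(ours$U, unname(ref$statistic))
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
})

test_that("Mann-Whitney exact and normal approximation agree at n = 10", {
  set.seed(7)
  worst <- 0
  for (rep in 1:20) {
    x <- rnorm(10); y <- rnorm(10) + runif(1, -1, 1)
    pe <- mann_whitney(x, y, exact_below = 12)$p
    pn <- mann_whitney(x, y, exact_below = 0)$p
    worst <- max(worst, abs(pe - pn))
  }
  expect_lt(worst, 0.01)
})

test_that("Spearman matches hand-ranked oracle and reference", {
  inc <- spearman(1:10, (1:10)^3)
  expect_equal(inc$rho, 1)
  dec <- spearman(1:10, -(1:10))
  expect_equal(dec$rho, -1)

  # tied 5-point fixture, midranks by hand:
  # x = (1, 2, 2, 3, 4)  -> rx = (1, 2.5, 2.5, 4, 5)
  # y = (10, 30, 20, 40, 40) -> ry = (1, 3, 2, 4.5, 4.5)
  x <- c(1, 2, 2, 3, 4); y <- c(10, 30, 20, 40, 40)
  rx <- c(1, 2.5, 2.5, 4, 5); ry <- c(1, 3, 2, 4.5, 4.5)
  hand_rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  res <- spearman(x, y)
  expect_equal(res$rho, hand_rho, tolerance = 1e-12)
  expect_equal(res$rho, unname(cor.test(x, y, method = "spearman",
                                        exact = FALSE)$estimate),
               tolerance = 1e-12)

  # invariance under strictly monotone transforms
  set.seed(3)
  a <- rnorm(40); b <- a + rnorm(40)
  base <- spearman(a, b)$rho
  expect_equal(spearman(exp(a), b)$rho, base, tolerance = 1e-12)
  expect_equal(spearman(rank(a), exp(b))$rho, base, tolerance = 1e-12)

  degen <- spearman(rep(1, 10), rnorm(10))
  expect_false(degen$defined)
  expect_error(spearman(1:2, 1:2), "n >= 3")
})

test_that("one-way ANOVA matches the hand-computed 3x3 fixture", {
  # groups {1,2,3}, {2,3,4}, {6,7,8}: SSB = 42, SSW = 6, F = 21
  res <- anova_oneway(list(c(1, 2, 3), c(2, 3, 4), c(6, 7, 8)))
  expect_equal(res$F, 21, tolerance = 1e-12)
  expect_equal(res$p, pf(21, 2, 6, lower.tail = FALSE), tolerance = 1e-12)

  # identical distributions across groups: F = 0, p = 1
  perm <- anova_oneway(list(c(1, 2, 3), c(3, 1, 2), c(2, 3, 1)))
  expect_equal(perm$F, 0, tolerance = 1e-12)
  expect_equal(perm$p, 1, tolerance = 1e-12)

  # complete separation with tiny jitter
  set.seed(5)
  sep <- anova_oneway(list(rnorm(3, 0, 1e-4), rnorm(3, 10, 1e-4),
                           rnorm(3, 20, 1e-4)))
  expect_lt(sep$p, 1e-6)
  expect_error(anova_oneway(list(1:3)), ">= 2 groups")
  expect_error(anova_oneway(list(1:3, 2)), "n >= 2")
})

test_that("node correlations recover generator coupling and flag nulls", {
  bc <- bulge_case(r0 = 2, A = 1, s0 = 20, sigma = 4, spacing = 0.7,
                   angular_res = 32)
  w <- make_wss_series(bc$mesh, bc$cl, flow_params(noise_sd = 0.01), seed = 2)
  maps <- list(TAWSS = tawss(w), OSI = osi(w), GON = gon(w), RRT = rrt(w))
  nv <- n_vertices(bc$mesh)
  set.seed(11)
  er <- 0.2 + 0.8 * rank(maps$RRT) / nv + rnorm(nv, sd = 0.05)
  seg <- bc$mesh$point_data$s >= 12 & bc$mesh$point_data$s <= 28
  nc <- node_correlations(er, maps, seg)
  expect_gt(nc$rho[nc$index == "RRT"], 0.3)
  expect_lt(nc$p[nc$index == "RRT"], 0.001)
  expect_lt(nc$rho[nc$index == "TAWSS"], 0)
  expect_equal(nc$strength[nc$index == "RRT"], "moderate")

  # null coupling: spurious |rho| stays small on large vertex counts
  set.seed(21)
  hits <- vapply(1:40, function(i) {
    abs(spearman(rnorm(5000), rnorm(5000))$rho) > 0.1
  }, logical(1))
  expect_lte(mean(hits), 0.05)

  const <- node_correlations(rep(0.5, nv), maps, seg)
  expect_false(any(const$defined))
})

test_that("cohort report emits the four tables with sane statistics", {
  set.seed(31)
  n <- 21
  types <- rep(c("fusiform", "dolichoectatic", "transitional"), each = 7)
  l <- c(rnorm(7, 14, 3), rnorm(7, 24, 4), rnorm(7, 30, 6))
  tab <- data.frame(
    case_id = sprintf("case%02d", 1:n), ifa_type = types,
    d_max = l / 2 + rnorm(n, 0, 1), l_max = l,
    kappa_max = runif(n, 0.05, 0.15), kappa_mean = runif(n, 0.03, 0.08),
    tau_max = runif(n, 0.3, 0.7), tau_mean = runif(n, 0.1, 0.3),
    cr_max = runif(n, 0.9, 1.2),
    enhancement_area = 10 * l + rnorm(n, 0, 20),
    proportion_enhanced = runif(n, 0.2, 0.6),
    TAWSS_max = runif(n, 1, 2), TAWSS_mean = runif(n, 0.2, 0.4),
    OSI_max = runif(n, 0.4, 0.5), OSI_mean = runif(n, 0.05, 0.15),
    GON_max = runif(n, 0.8, 1), GON_mean = runif(n, 0.1, 0.3),
    RRT_max = runif(n, 50, 250), RRT_mean = runif(n, 2, 9),
    TAWSS_enh = runif(n, 0.1, 0.2), TAWSS_non = runif(n, 0.25, 0.45),
    OSI_enh = runif(n, 0.1, 0.2), OSI_non = runif(n, 0.02, 0.08),
    GON_enh = runif(n, 0.3, 0.5), GON_non = runif(n, 0.1, 0.2),
    RRT_enh = runif(n, 5, 9), RRT_non = runif(n, 1, 4),
    rho_TAWSS = runif(n, -0.6, -0.1), rho_OSI = runif(n, 0.1, 0.5),
    rho_GON = runif(n, 0.0, 0.4), rho_RRT = runif(n, 0.2, 0.6),
    stringsAsFactors = FALSE)
  out_dir <- withr::local_tempdir()
  rep1 <- cohort_report(tab, out_dir = out_dir, provenance = "test run")
  for (f in c("cohort_table1.csv", "region_compare.csv",
              "node_correlations.csv", "size_correlation.csv"))
    expect_true(file.exists(file.path(out_dir, f)))
  t1 <- rep1$cohort_table1
  expect_true(all(c("variable", "anova_p", "shapiro_p") %in% names(t1)))
  expect_equal(nrow(rep1$region_compare), 4L)
  expect_true(all(rep1$region_compare$mann_whitney_p < 0.05))
  # size coupling built into the fixture is recovered
  sz <- rep1$size_correlation
  expect_gt(sz$rho[sz$size_variable == "l_max"], 0.5)
  expect_lt(sz$p[sz$size_variable == "l_max"], 0.05)
  # l_max differs by type by construction
  expect_lt(t1$anova_p[t1$variable == "l_max"], 0.05)

  # identical cases give uninformative ANOVA rows
  tab2 <- tab
  for (v in c("d_max", "l_max"))
    tab2[[v]] <- rep(tab[[v]][1:7], 3)
  rep2 <- cohort_report(tab2)
  expect_gt(rep2$cohort_table1$anova_p[rep2$cohort_table1$variable ==
                                         "d_max"], 0.9)
})
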