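# shared decomposition fixture: model trained on a clean reference cohort,
# patients with a planted shift, site-matched controls
decomp_fixture <- function(g_scz = -0.7, n_pat = 40, n_con = 40, seed = 21) {
  gt <- ground_truth(default_atlas, noise_sd = 0, seed = seed)
  ref <- simulate_cohort(c(HC = 80), gt, default_atlas, score_noise_sd = 0,
                         seed = seed + 1)
  model <- fit_vbsr(ref$fc, ref$cohort$wma_true)
  gt$delta$SCZ <- delta_for_effect(gt, g_scz)
  test <- simulate_cohort(stats::setNames(c(n_con, n_pat), c("HC", "SCZ")),
                          gt, default_atlas, seed = seed + 2)
  is_pat <- test$cohort$diagnosis == "SCZ"
  al <- align_to_reference(test$fc[!is_pat, ], test$fc[is_pat, ], ref$fc)
  list(gt = gt, ref = ref, model = model, aligned = al)
}

test_that("alignment maps control distributions onto the reference and is invertible", {
  set.seed(31)
  con <- matrix(rnorm(50 * 4), 50, 4)
  pat <- matrix(rnorm(30 * 4, 0.3), 30, 4)
  ref <- matrix(rnorm(80 * 4, 5, 2), 80, 4)
  al <- align_to_reference(con, pat, ref)
  expect_equal(colMeans(al$controls), colMeans(ref), tolerance = 1e-10)
  expect_equal(apply(al$controls, 2, sd), apply(ref, 2, sd), tolerance = 1e-10)
  # patients use the control-derived map: N(0,1) -> N(5,2) sends 2 to 5 + 2*z
  z <- (2 - al$map$mu_src[1]) / al$map$sd_src[1]
  expect_equal(al$patients[1, 1],
               al$map$mu_ref[1] + al$map$sd_ref[1] *
                 (pat[1, 1] - al$map$mu_src[1]) / al$map$sd_src[1])
  # round-trip: un-aligning recovers the inputs
  back <- sweep(sweep(sweep(sweep(al$patients, 2, al$map$mu_ref), 2,
                            al$map$sd_ref, `/`), 2, al$map$sd_src, `*`),
                2, al$map$mu_src, `+`)
  expect_equal(back, pat, tolerance = 1e-12)
  # identity when source equals reference
  al2 <- align_to_reference(con, pat, con)
  expect_equal(al2$patients, pat, tolerance = 1e-12)
  con0 <- con; con0[, 2] <- 1
  expect_error(align_to_reference(con0, pat, ref), "zero control SD")
})

test_that("explicit alignment arithmetic: N(0,1) source to N(5,2) reference", {
  # large samples so source moments are (0,1) and reference (5,2) closely
  set.seed(32)
  con <- matrix(rnorm(2e4), ncol = 1)
  pat <- matrix(c(1, 2), ncol = 1)
  ref <- matrix(rnorm(2e4, 5, 2), ncol = 1)
  al <- align_to_reference(con, pat, ref)
  expect_equal(al$patients[, 1], c(7, 9), tolerance = 0.1)
})

test_that("D-scores are the weighted-FC deviations and conserve the predicted deviation", {
  fx <- decomp_fixture()
  D <- d_scores(fx$model, fx$aligned$patients, fx$aligned$controls)
  expect_equal(ncol(D), length(fx$model$support))
  # conservation: row sums equal predicted-WMA deviation from control mean
  dev <- predict(fx$model, fx$aligned$patients) -
    mean(predict(fx$model, fx$aligned$controls))
  expect_equal(unname(rowSums(D)), dev, tolerance = 1e-10)
  # hand arithmetic: w = 2, x_p = 0.5, mean control x = 0.3 -> D = 0.4
  m <- fx$model
  m$support <- 1L; m$support_labels <- names(m$weights)[1]
  m$weights[] <- 0; m$weights[1] <- 2
  P <- matrix(0.5, 1, length(m$weights)); Cm <- matrix(0.3, 4, length(m$weights))
  expect_equal(as.numeric(d_scores(m, P, Cm)), 0.4)
  # patient at the control mean -> all D zero
  Dm <- d_scores(fx$model, fx$aligned$controls[1, , drop = FALSE] * 0 +
                   rep(colMeans(fx$aligned$controls), each = 1),
                 fx$aligned$controls)
  expect_lt(max(abs(Dm)), 1e-12)
})

test_that("Z-scores standardize by control weighted-FC SD; control self-Z is standard", {
  fx <- decomp_fixture()
  D <- d_scores(fx$model, fx$aligned$patients, fx$aligned$controls)
  Z <- z_scores(D, fx$aligned$controls, fx$model)
  expect_equal(dim(Z), dim(D))
  # D = 0.4 with control SD 0.2 -> Z = 2 (construct directly)
  idx <- fx$model$support[1]
  w <- fx$model$weights[idx]
  sdc <- sd(fx$aligned$controls[, idx] * w)
  expect_equal(Z[, 1], D[, 1] / sdc)
  # controls' own Z: mean 0, SD 1 per connection by construction
  Dc <- d_scores(fx$model, fx$aligned$controls, fx$aligned$controls)
  Zc <- z_scores(Dc, fx$aligned$controls, fx$model)
  expect_lt(max(abs(colMeans(Zc))), 1e-10)
  expect_equal(unname(apply(Zc, 2, sd)), rep(1, ncol(Zc)), tolerance = 1e-10)
})

test_that("planted shift on one connection concentrates the mean D-score there", {
  gt <- ground_truth(default_atlas, noise_sd = 0, seed = 41)
  ref <- simulate_cohort(c(HC = 80), gt, default_atlas, score_noise_sd = 0, seed = 42)
  model <- fit_vbsr(ref$fc, ref$cohort$wma_true)
  j <- gt$support[which.max(abs(gt$w_true[gt$support]))]
  delta <- numeric(171); delta[j] <- -0.15
  gt$delta$SCZ <- delta
  test <- simulate_cohort(c(HC = 150, SCZ = 150), gt, default_atlas, seed = 43)
  is_pat <- test$cohort$diagnosis == "SCZ"
  al <- align_to_reference(test$fc[!is_pat, ], test$fc[is_pat, ], ref$fc)
  D <- d_scores(model, al$patients, al$controls)
  md <- abs(colMeans(D))
  target_col <- which(model$support == j)
  expect_gt(md[target_col], 5 * max(md[-target_col]))
})

test_that("permutation two-way ANOVA agrees with exhaustive enumeration for tiny n", {
  set.seed(51)
  Z <- matrix(rnorm(5 * 3), 5, 3)
  lab <- c("A", "A", "B", "B", "B")
  res <- perm_two_way_anova(Z, lab, n_perm_main = 1000, n_perm_inter = 200, seed = 1)
  expect_equal(res$n_perm_main, 120)  # 5! exhaustive
  # independent oracle: enumerate all label permutations, one-way F on subject means
  sm <- rowMeans(Z)
  perms <- list()
  idx <- 1:5
  f_obs <- oracle_main_F(sm, lab)
  count <- 0; total <- 0
  rec <- function(rem, acc) {
    if (!length(rem)) {
      total <<- total + 1
      if (oracle_main_F(sm, lab[acc]) >= f_obs - 1e-12) count <<- count + 1
      return()
    }
    for (k in seq_along(rem)) rec(rem[-k], c(acc, rem[k]))
  }
  rec(idx, integer(0))
  expect_equal(res$p_main, count / total)
})

test_that("planted diagnosis offsets drive the main effect; crossed patterns drive the interaction", {
  set.seed(52)
  n <- 30; C <- 6
  base <- matrix(rnorm(2 * n * C), 2 * n, C)
  lab <- rep(c("SCZ", "ASD"), each = n)
  # constant offset for one diagnosis on all connections -> main effect only
  zm <- base; zm[lab == "SCZ", ] <- zm[lab == "SCZ", ] - 1.2
  rm_ <- perm_two_way_anova(zm, lab, n_perm_main = 500, n_perm_inter = 300, seed = 2)
  expect_lt(rm_$p_main, 0.01)
  expect_gt(rm_$p_interaction, 0.05)
  expect_equal(rm_$pairwise$p[1], rm_$p_main)  # two groups: pairwise = main
  # crossed pattern with zero marginals -> interaction only
  zi <- base
  zi[lab == "SCZ", 1:3] <- zi[lab == "SCZ", 1:3] + 1.2
  zi[lab == "SCZ", 4:6] <- zi[lab == "SCZ", 4:6] - 1.2
  zi[lab == "ASD", 1:3] <- zi[lab == "ASD", 1:3] - 1.2
  zi[lab == "ASD", 4:6] <- zi[lab == "ASD", 4:6] + 1.2
  ri <- perm_two_way_anova(zi, lab, n_perm_main = 500, n_perm_inter = 300, seed = 3)
  expect_lt(ri$p_interaction, 0.01)
  expect_gt(ri$p_main, 0.05)
  # the alternative global shuffling scheme also detects it
  rg <- perm_two_way_anova(zi, lab, n_perm_main = 500, n_perm_inter = 300,
                           seed = 4, interaction_scheme = "global")
  expect_lt(rg$p_interaction, 0.01)
  expect_error(perm_two_way_anova(zm, rep("A", 2 * n)), "2 diagnoses")
})

test_that("Kruskal-Wallis per connection matches the rank oracle and controls FDR", {
  # hand-computed: {1,2,3} vs {4,5,6} -> H = 3.857
  Z1 <- matrix(c(1, 2, 3, 4, 5, 6), ncol = 1)
  lab <- rep(c("A", "B"), each = 3)
  kw <- kw_per_connection_fdr(Z1, lab)
  expect_equal(kw$chisq, 12 / (6 * 7) * (3 * (2 - 3.5)^2 + 3 * (5 - 3.5)^2),
               tolerance = 1e-12)
  expect_equal(kw$chisq, 3.857, tolerance = 1e-3)
  # one separated connection among nulls is the one flagged
  set.seed(53)
  Z2 <- matrix(rnorm(100 * 8), 100, 8)
  lab2 <- rep(c("SCZ", "MDD"), each = 50)
  Z2[lab2 == "SCZ", 4] <- Z2[lab2 == "SCZ", 4] + 1.5
  kw2 <- kw_per_connection_fdr(Z2, lab2)
  expect_true(kw2$significant[4])
  expect_equal(sum(kw2$significant[-4]), 0)
  # all-tied column degrades gracefully
  Z3 <- cbind(Z2[, 1], 1)
  expect_warning(kw3 <- kw_per_connection_fdr(Z3, lab2), "all-tied")
  expect_equal(kw3$chisq[2], 0)
  expect_equal(kw3$p[2], 1)
})

test_that("KS comparison of chi-square distributions behaves at the extremes", {
  x <- c(1, 2, 3, 4, 5)
  same <- ks_model_vs_other_connections(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  disj <- ks_model_vs_other_connections(1:5, 11:15)
  expect_equal(disj$statistic, 1)
  expect_error(ks_model_vs_other_connections(numeric(0), x), "nonempty")
})

test_that("cluster summation keeps only bridging connections and double-counts endpoints", {
  a <- default_atlas
  tab <- fc_feature_table(a)
  # single connection bridging two clusters, mean D = -0.3
  bridge <- tab[tab$type == "between" &
                  a$cluster_of[tab$net_i] != a$cluster_of[tab$net_j], ][1, ]
  D <- matrix(-0.3, 4, 1, dimnames = list(NULL, bridge$label))
  out <- cluster_summed_dscores(D, a, rep("SCZ", 4))
  expect_equal(nrow(out), 2)
  expect_equal(out$summed_d, c(-0.3, -0.3))
  expect_setequal(out$cluster,
                  a$cluster_names[c(a$cluster_of[bridge$net_i],
                                    a$cluster_of[bridge$net_j])])
  # within-cluster-only connections produce an empty summary
  within_cl <- tab[tab$type == "between" &
                     a$cluster_of[tab$net_i] == a$cluster_of[tab$net_j], ][1, ]
  D2 <- matrix(1, 4, 1, dimnames = list(NULL, within_cl$label))
  out2 <- cluster_summed_dscores(D2, a, rep("SCZ", 4))
  expect_equal(nrow(out2), 0)
  # clusters untouched by any selected connection are absent
  expect_false(any(setdiff(a$cluster_names, out$cluster) %in% out$cluster))
  expect_error(cluster_summed_dscores(
    matrix(1, 2, 1, dimnames = list(NULL, "nonsense")), a, rep("HC", 2)),
    "not present")
})
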