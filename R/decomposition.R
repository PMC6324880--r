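#' Align cohort FC distributions to a reference cohort
#'
#' For each connection, the control group's FC distribution is mapped onto the
#' reference (training-cohort) distribution by the linear transform
#' `x' = (x - mu_src) / sd_src * sd_ref + mu_ref`, where source mean/SD come
#' from the controls; the identical control-derived transform is then applied
#' to the patients (never a map fitted on the patients themselves). This
#' removes site/scanner offsets before D-score computation.
#'
#' @param fc_controls,fc_patients subjects x features matrices, same feature
#'   order.
#' @param fc_reference reference subjects x features matrix (same features).
#' @return list with `controls`, `patients` (aligned matrices) and `map`
#'   (data.frame: `mu_src`, `sd_src`, `mu_ref`, `sd_ref` per feature).
#' @export
align_to_reference <- function(fc_controls, fc_patients, fc_reference) {
  fc_controls <- as.matrix(fc_controls)
  fc_patients <- as.matrix(fc_patients)
  fc_reference <- as.matrix(fc_reference)
  p <- ncol(fc_controls)
  if (ncol(fc_patients) != p || ncol(fc_reference) != p)
    stop("all inputs must share the same feature columns")
  if (nrow(fc_controls) < 2L) stop("need at least 2 control subjects")
  mu_src <- colMeans(fc_controls)
  sd_src <- apply(fc_controls, 2L, stats::sd)
  if (any(sd_src == 0))
    stop("zero control SD at connection(s): ",
         paste(.feature_names(fc_controls)[sd_src == 0], collapse = ", "))
  mu_ref <- colMeans(fc_reference)
  sd_ref <- apply(fc_reference, 2L, stats::sd)
  apply_map <- function(m)
    sweep(sweep(sweep(sweep(m, 2L, mu_src), 2L, sd_src, `/`),
                2L, sd_ref, `*`), 2L, mu_ref, `+`)
  map <- data.frame(feature = .feature_names(fc_controls),
                    mu_src = mu_src, sd_src = sd_src,
                    mu_ref = mu_ref, sd_ref = sd_ref,
                    stringsAsFactors = FALSE, row.names = NULL)
  list(controls = apply_map(fc_controls), patients = apply_map(fc_patients),
       map = map)
}

.feature_names <- function(m) {
  if (is.null(colnames(m))) sprintf("feature_%03d", seq_len(ncol(m))) else colnames(m)
}

#' Per-connection weighted-FC deviations (D-scores)
#'
#' For each patient p and each model-selected connection i,
#' `D[i, p] = w_i x[i, p] - mean_c(w_i x[i, c])`: the patient's weighted FC
#' minus the control-group mean of weighted FC. Because the model is a linear
#' weighted summation, the D-scores of a patient sum exactly to that
#' patient's predicted-WMA deviation from the control mean (the intercept
#' cancels).
#'
#' @param model a fitted `wma_model`.
#' @param aligned_patients,aligned_controls subjects x features FC matrices
#'   (typically after [align_to_reference()]).
#' @return matrix patients x selected connections (colnames = support labels),
#'   with attribute `control_mean_wfc` (per-connection control mean of
#'   weighted FC).
#' @export
d_scores <- function(model, aligned_patients, aligned_controls) {
  stopifnot(inherits(model, "wma_model"))
  aligned_patients <- as.matrix(aligned_patients)
  aligned_controls <- as.matrix(aligned_controls)
  if (nrow(aligned_controls) < 1L) stop("empty control group")
  p <- length(model$weights)
  if (ncol(aligned_patients) != p || ncol(aligned_controls) != p)
    stop("FC matrices must match the model's feature count")
  idx <- model$support
  if (length(idx) == 0L) stop("model has an empty support")
  w <- model$weights[idx]
  wfc_pat <- sweep(aligned_patients[, idx, drop = FALSE], 2L, w, `*`)
  wfc_con <- sweep(aligned_controls[, idx, drop = FALSE], 2L, w, `*`)
  ctrl_mean <- colMeans(wfc_con)
  D <- sweep(wfc_pat, 2L, ctrl_mean)
  colnames(D) <- model$support_labels
  attr(D, "control_mean_wfc") <- ctrl_mean
  D
}

#' Standardized D-scores (Z-scores)
#'
#' `Z[i, p] = D[i, p] / SD_c(w_i x[i, c])`: each D-score divided by the
#' control group's standard deviation of weighted FC at that connection. By
#' construction the controls' own Z-scores have mean 0 and SD 1 per
#' connection.
#'
#' @param d a D-score matrix from [d_scores()].
#' @param aligned_controls the control FC matrix used for the D-scores.
#' @param model the fitted `wma_model`.
#' @return matrix patients x selected connections.
#' @export
z_scores <- function(d, aligned_controls, model) {
  stopifnot(inherits(model, "wma_model"))
  aligned_controls <- as.matrix(aligned_controls)
  idx <- model$support
  w <- model$weights[idx]
  wfc_con <- sweep(aligned_controls[, idx, drop = FALSE], 2L, w, `*`)
  sd_con <- apply(wfc_con, 2L, stats::sd)
  if (any(sd_con == 0))
    stop("zero control SD of weighted FC at connection(s): ",
         paste(model$support_labels[sd_con == 0], collapse = ", "))
  sweep(d, 2L, sd_con, `/`)
}

# mixed-design two-way F statistics: diagnosis between subjects,
# connection within subjects; rows of Z are subjects, columns connections
.two_way_F <- function(Z, g) {
  N <- nrow(Z); C <- ncol(Z)
  ng <- tabulate(g)
  G <- length(ng)
  grand <- mean(Z)
  sub_mean <- rowMeans(Z)
  m_g <- as.numeric(rowsum(sub_mean, g)) / ng
  ss_diag <- C * sum(ng * (m_g - grand)^2)
  ss_subj <- C * sum((sub_mean - m_g[g])^2)
  f_main <- (ss_diag / (G - 1)) / (ss_subj / (N - G))
  cell <- rowsum(Z, g) / ng                     # G x C cell means
  conn_mean <- colMeans(Z)
  dev <- sweep(sweep(cell, 1L, m_g), 2L, conn_mean) + grand
  ss_int <- sum(ng * dev^2)
  resid <- Z - sub_mean - cell[g, , drop = FALSE] + m_g[g]
  ss_err <- sum(resid^2)
  f_inter <- (ss_int / ((G - 1) * (C - 1))) / (ss_err / ((N - G) * (C - 1)))
  c(main = f_main, interaction = f_inter)
}

# main-effect F only, from precomputed subject means (cheap permutation path)
.main_F <- function(sub_mean, g, ng) {
  N <- length(sub_mean); G <- length(ng)
  m_g <- as.numeric(rowsum(sub_mean, g)) / ng
  grand <- mean(sub_mean)
  ss_diag <- sum(ng * (m_g - grand)^2)
  ss_subj <- sum((sub_mean - m_g[g])^2)
  (ss_diag / (G - 1)) / (ss_subj / (N - G))
}

.perm_tail_p <- function(obs, null, exact) {
  tol <- 1e-12
  hits <- sum(null >= obs - tol)
  if (exact) hits / length(null) else (1 + hits) / (1 + length(null))
}

#' Permutation two-way ANOVA of Z-scores (diagnosis x connection)
#'
#' Observed F statistics come from a mixed two-way decomposition with
#' diagnosis as a between-participant factor and connection as a
#' within-participant factor. Because Z-score variances are heterogeneous
#' across diagnoses and connections, p-values are obtained by permutation:
#' the main effect shuffles whole subjects' diagnosis labels (rows move
#' intact); the interaction null additionally permutes connection labels,
#' either independently within each subject (`interaction_scheme =
#' "within_subject"`, default) or by one shared column permutation
#' (`"global"`). Post-hoc pairwise main effects shuffle labels within each
#' diagnosis pair. For `<= 6` subjects the main-effect null is enumerated
#' exhaustively.
#'
#' @param Z patients x connections Z-score matrix.
#' @param diagnosis_labels diagnosis per patient (factor or character).
#' @param n_perm_main shuffles for main and pairwise effects (default 10000).
#' @param n_perm_inter shuffles for the interaction (default 100000).
#' @param seed integer seed.
#' @param interaction_scheme connection-label shuffling scheme, see above.
#' @return object of class `perm_anova_result`: list with `f_main`, `p_main`,
#'   `f_interaction`, `p_interaction`, `pairwise` (data.frame), `n_perm_main`,
#'   `n_perm_inter`, `seed`, `interaction_scheme`.
#' @export
perm_two_way_anova <- function(Z, diagnosis_labels, n_perm_main = 10000L,
                               n_perm_inter = 100000L, seed = 1L,
                               interaction_scheme = c("within_subject", "global")) {
  interaction_scheme <- match.arg(interaction_scheme)
  Z <- as.matrix(Z)
  g <- factor(diagnosis_labels)
  if (nrow(Z) != length(g)) stop("one diagnosis label per row of Z is required")
  if (nlevels(g) < 2L) stop("need at least 2 diagnoses")
  if (ncol(Z) < 2L) stop("need at least 2 connections")
  if (min(n_perm_main, n_perm_inter) < 100L) stop("permutation counts must be >= 100")
  N <- nrow(Z); C <- ncol(Z)
  gi <- as.integer(g); ng <- tabulate(gi)
  obs <- .two_way_F(Z, gi)

  set.seed(seed)
  sub_mean <- rowMeans(Z)
  exact_main <- factorial(N) <= n_perm_main
  if (exact_main) {
    perms <- .all_perms(N)
    null_main <- apply(perms, 1L, function(ix) .main_F(sub_mean, gi[ix], ng))
  } else {
    null_main <- vapply(seq_len(n_perm_main), function(r)
      .main_F(sub_mean, gi[sample.int(N)], ng), numeric(1))
  }
  p_main <- .perm_tail_p(obs["main"], null_main, exact_main)

  null_inter <- vapply(seq_len(n_perm_inter), function(r) {
    gp <- gi[sample.int(N)]
    if (interaction_scheme == "within_subject") {
      cols <- vapply(seq_len(N), function(s) sample.int(C), integer(C))
      Zp <- matrix(Z[cbind(rep(seq_len(N), each = C), as.vector(cols))],
                   N, C, byrow = TRUE)
    } else {
      Zp <- Z[, sample.int(C), drop = FALSE]
    }
    .two_way_F(Zp, gp)[["interaction"]]
  }, numeric(1))
  p_inter <- .perm_tail_p(obs["interaction"], null_inter, exact = FALSE)

  lev <- levels(g)
  pair_rows <- list()
  for (i in seq_len(nlevels(g) - 1L)) for (j in (i + 1L):nlevels(g)) {
    sel <- gi %in% c(i, j)
    sm <- sub_mean[sel]
    gg <- as.integer(factor(gi[sel]))
    nn <- tabulate(gg)
    f_obs <- .main_F(sm, gg, nn)
    npair <- length(sm)
    exact_pair <- factorial(npair) <= n_perm_main
    if (exact_pair) {
      pp <- .all_perms(npair)
      nullp <- apply(pp, 1L, function(ix) .main_F(sm, gg[ix], nn))
    } else {
      nullp <- vapply(seq_len(n_perm_main), function(r)
        .main_F(sm, gg[sample.int(npair)], nn), numeric(1))
    }
    pair_rows[[length(pair_rows) + 1L]] <-
      data.frame(group1 = lev[i], group2 = lev[j], f = f_obs,
                 p = .perm_tail_p(f_obs, nullp, exact_pair),
                 stringsAsFactors = FALSE)
  }

  structure(list(f_main = unname(obs["main"]), p_main = p_main,
                 f_interaction = unname(obs["interaction"]),
                 p_interaction = p_inter,
                 pairwise = do.call(rbind, pair_rows),
                 n_perm_main = if (exact_main) length(null_main) else n_perm_main,
                 n_perm_inter = n_perm_inter, seed = seed,
                 interaction_scheme = interaction_scheme),
            class = "perm_anova_result")
}

#' @export
print.perm_anova_result <- function(x, ...) {
  cat(sprintf("permutation two-way ANOVA: F_main = %.3f (p = %.4g, %d perms); F_interaction = %.3f (p = %.4g, %d perms)\n",
              x$f_main, x$p_main, x$n_perm_main,
              x$f_interaction, x$p_interaction, x$n_perm_inter))
  invisible(x)
}

#' Per-connection Kruskal-Wallis tests with BH-FDR correction
#'
#' Tie-corrected Kruskal-Wallis chi-square of diagnosis per connection
#' (column of Z), with Benjamini-Hochberg false-discovery-rate flags at
#' level `q`. All-tied columns get H = 0, p = 1 with a warning.
#'
#' @param Z patients x connections matrix.
#' @param diagnosis_labels diagnosis per patient.
#' @param q FDR level (default 0.05).
#' @return data.frame: `connection`, `chisq`, `df`, `p`, `p_fdr`, `significant`.
#' @export
kw_per_connection_fdr <- function(Z, diagnosis_labels, q = 0.05) {
  Z <- as.matrix(Z)
  g <- factor(diagnosis_labels)
  if (nlevels(g) < 2L) stop("need at least 2 diagnoses")
  cn <- .feature_names(Z)
  res <- lapply(seq_len(ncol(Z)), function(j) {
    col <- Z[, j]
    if (length(unique(col)) == 1L) {
      warning("connection ", cn[j], " is all-tied; H set to 0, p to 1")
      return(c(h = 0, df = nlevels(g) - 1L, p = 1))
    }
    k <- stats::kruskal.test(col, g)
    c(h = unname(k$statistic), df = unname(k$parameter), p = k$p.value)
  })
  res <- do.call(rbind, res)
  out <- data.frame(connection = cn, chisq = res[, "h"], df = res[, "df"],
                    p = res[, "p"],
                    p_fdr = stats::p.adjust(res[, "p"], method = "BH"),
                    stringsAsFactors = FALSE)
  out$significant <- out$p_fdr < q
  out
}

#' Compare chi-square distributions of model vs non-model connections
#'
#' Two-sample Kolmogorov-Smirnov test asking whether the per-connection
#' diagnosis-effect chi-square values of the model's selected connections are
#' distributed differently from those of the remaining connections.
#'
#' @param chisq_model chi-square values at the model's connections.
#' @param chisq_other chi-square values at all other connections.
#' @return list with `statistic` (KS D), `p`.
#' @export
ks_model_vs_other_connections <- function(chisq_model, chisq_other) {
  if (length(chisq_model) == 0L || length(chisq_other) == 0L)
    stop("both samples must be nonempty")
  kt <- suppressWarnings(stats::ks.test(chisq_model, chisq_other))
  list(statistic = unname(kt$statistic), p = kt$p.value)
}

#' Cluster-level summed D-scores over between-cluster connections
#'
#' Averages each selected connection's D-score across the participants of
#' each diagnosis, keeps only connections bridging two different clusters,
#' and for every cluster sums the mean D-scores of the bridging connections
#' that have a network node in that cluster (a connection between clusters A
#' and B contributes to both). Clusters touched by no selected bridging
#' connection are absent from the output.
#'
#' @param D D-score matrix from [d_scores()] (colnames are canonical feature
#'   labels).
#' @param atlas the `wma_atlas` defining the network -> cluster map.
#' @param diagnosis_labels diagnosis per patient (row of D).
#' @return data.frame: `cluster`, `diagnosis`, `summed_d`.
#' @export
cluster_summed_dscores <- function(D, atlas, diagnosis_labels) {
  stopifnot(inherits(atlas, "wma_atlas"))
  D <- as.matrix(D)
  g <- factor(diagnosis_labels)
  if (nrow(D) != length(g)) stop("one diagnosis label per row of D is required")
  tab <- fc_feature_table(atlas)
  m <- match(colnames(D), tab$label)
  if (anyNA(m))
    stop("connection(s) not present in the atlas feature table: ",
         paste(colnames(D)[is.na(m)], collapse = ", "))
  cl_i <- atlas$cluster_of[tab$net_i[m]]
  cl_j <- atlas$cluster_of[tab$net_j[m]]
  bridging <- cl_i != cl_j
  if (!any(bridging))
    return(data.frame(cluster = character(0), diagnosis = character(0),
                      summed_d = numeric(0), stringsAsFactors = FALSE))
  rows <- list()
  for (d in levels(g)) {
    mean_d <- colMeans(D[g == d, , drop = FALSE])
    for (cl in sort(unique(c(cl_i[bridging], cl_j[bridging])))) {
      touch <- bridging & (cl_i == cl | cl_j == cl)
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = atlas$cluster_names[cl], diagnosis = d,
        summed_d = sum(mean_d[touch]), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
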