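#' Canonical 18-network parcellation used for network-level connectivity
#'
#' The default atlas mirrors an 18-network whole-brain intrinsic-connectivity
#' parcellation grouped into seven functional clusters (fronto-parietal,
#' motor/visuospatial, emotion/interoception, audition/speech, visual,
#' cerebellum, default-mode). Each network is populated with a fixed number of
#' voxels; voxel membership is what [compute_fc()] aggregates over.
#'
#' @param n_networks number of networks (>= 2).
#' @param voxels_per_network voxels assigned to each network (>= 2; a single
#'   count recycled, or a vector of length `n_networks`).
#' @param seed integer seed; the atlas itself is deterministic, the seed is
#'   recorded so downstream simulators can derive reproducible streams.
#' @return an object of class `wma_atlas`: list with `n_networks`,
#'   `network_names`, `voxels_per_network`, `cluster_of` (named integer),
#'   `cluster_names`, `voxel_network` (voxel -> network index) and `seed`.
#' @examples
#' atlas <- make_atlas()
#' atlas$n_networks            # 18
#' length(fc_feature_labels(atlas))  # 171
#' @export
make_atlas <- function(n_networks = 18L, voxels_per_network = 20L, seed = 1L) {
  n_networks <- as.integer(n_networks)
  if (is.na(n_networks) || n_networks < 2L)
    stop("`n_networks` must be an integer >= 2")
  voxels_per_network <- as.integer(voxels_per_network)
  if (length(voxels_per_network) == 1L)
    voxels_per_network <- rep(voxels_per_network, n_networks)
  if (length(voxels_per_network) != n_networks || any(is.na(voxels_per_network)) ||
      any(voxels_per_network < 2L))
    stop("`voxels_per_network` must give >= 2 voxels for every network")

  if (n_networks == 18L) {
    network_names <- .default_network_names
    cluster_id <- .default_cluster_of
  } else {
    network_names <- sprintf("network_%02d", seq_len(n_networks))
    n_cl <- min(7L, n_networks)
    cluster_id <- ((seq_len(n_networks) - 1L) %% n_cl) + 1L
  }
  cluster_names <- .cluster_names[sort(unique(cluster_id))]
  names(cluster_id) <- network_names

  structure(list(
    n_networks = n_networks,
    network_names = network_names,
    voxels_per_network = voxels_per_network,
    cluster_of = cluster_id,
    cluster_names = .cluster_names,
    voxel_network = rep(seq_len(n_networks), voxels_per_network),
    seed = as.integer(seed)
  ), class = "wma_atlas")
}

# 18 canonical networks; ranks/names follow the BrainMap-style grouping.
.default_network_names <- c(
  "left_fronto_parietal",            # 1
  "middle_frontal_parietal",         # 2
  "supplemental_motor",              # 3
  "right_fronto_parietal",           # 4
  "cingulo_opercular",               # 5
  "lateral_temporal",                # 6
  "lateral_occipital",               # 7
  "basal_ganglia",                   # 8
  "sensorimotor_mouth",              # 9
  "midbrain",                        # 10
  "sensorimotor_hand",               # 11
  "cerebellum",                      # 12
  "medial_prefrontal",               # 13
  "orbitofrontal",                   # 14
  "auditory",                        # 15
  "precuneus_posterior_cingulate",   # 16
  "primary_visual",                  # 17
  "superior_parietal"                # 18
)

.cluster_names <- c("fronto_parietal", "motor_visuospatial",
                    "emotion_interoception", "audition_speech", "visual",
                    "cerebellum", "default_mode")

.default_cluster_of <- c(1L, 1L, 2L, 1L, 3L, 4L, 5L, 3L, 2L, 3L, 2L, 6L,
                         7L, 3L, 4L, 7L, 5L, 2L)

#' @export
print.wma_atlas <- function(x, ...) {
  cat(sprintf("wma_atlas: %d networks, %d voxels, %d clusters, %d FC features\n",
              x$n_networks, length(x$voxel_network),
              length(unique(x$cluster_of)), n_fc_features(x$n_networks)))
  invisible(x)
}

#' Number of network-level FC features for an n-network atlas
#'
#' `n` within-network features plus `n(n-1)/2` between-network features;
#' 171 for the default 18-network atlas.
#'
#' @param n_networks network count or a `wma_atlas`.
#' @return integer feature count.
#' @export
n_fc_features <- function(n_networks) {
  if (inherits(n_networks, "wma_atlas")) n_networks <- n_networks$n_networks
  n <- as.integer(n_networks)
  n + (n * (n - 1L)) %/% 2L
}

#' Canonical FC feature table: index, type and network pair
#'
#' The canonical ordering places the `n` within-network features first
#' (networks 1..n), then the between-network pairs (i, j), i < j, in
#' lexicographic order.
#'
#' @param atlas a `wma_atlas` (or an integer network count).
#' @return data.frame with columns `index`, `type` ("within"/"between"),
#'   `net_i`, `net_j` (equal for within features) and `label`.
#' @export
fc_feature_table <- function(atlas) {
  if (inherits(atlas, "wma_atlas")) {
    n <- atlas$n_networks; nm <- atlas$network_names
  } else {
    n <- as.integer(atlas); nm <- sprintf("network_%02d", seq_len(n))
  }
  within <- data.frame(index = seq_len(n), type = "within",
                       net_i = seq_len(n), net_j = seq_len(n),
                       stringsAsFactors = FALSE)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  between <- data.frame(index = n + seq_len(nrow(pairs)), type = "between",
                        net_i = pairs[, 1L], net_j = pairs[, 2L],
                        stringsAsFactors = FALSE)
  tab <- rbind(within, between)
  tab$label <- ifelse(tab$type == "within",
                      paste0("within.", nm[tab$net_i]),
                      paste0("between.", nm[tab$net_i], ".", nm[tab$net_j]))
  tab
}

#' Canonical FC feature labels
#' @inheritParams fc_feature_table
#' @return character vector of feature labels in canonical order.
#' @export
fc_feature_labels <- function(atlas) fc_feature_table(atlas)$label

#' Map a canonical feature index to its (type, i, j) description and back
#'
#' @param atlas a `wma_atlas` or network count.
#' @param index canonical feature index (1-based).
#' @return `fc_feature_info`: one-row data.frame for the index;
#'   `fc_feature_index`: the canonical index of a (net_i, net_j) pair
#'   (i == j selects the within-network feature).
#' @export
fc_feature_info <- function(atlas, index) {
  tab <- fc_feature_table(atlas)
  if (any(index < 1L | index > nrow(tab))) stop("feature index out of range")
  tab[index, , drop = FALSE]
}

#' @rdname fc_feature_info
#' @param net_i,net_j network indices.
#' @export
fc_feature_index <- function(atlas, net_i, net_j) {
  n <- if (inherits(atlas, "wma_atlas")) atlas$n_networks else as.integer(atlas)
  if (any(net_i < 1L | net_i > n | net_j < 1L | net_j > n))
    stop("network index out of range")
  i <- pmin(net_i, net_j); j <- pmax(net_i, net_j)
  ifelse(i == j, i,
         # between-pair (i,j), i<j, lexicographic rank offset by n within slots
         n + (i - 1L) * n - (i * (i - 1L)) %/% 2L + (j - i))
}
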