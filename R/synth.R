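#' Simulation configuration
#'
#' Defaults emulate the study design the package targets: six biological
#' replicates per group, 96 detected ginsenoside features of which 21
#' are differentially abundant, lognormal peak areas with multiplicative
#' group effects, and ppm-scale mass error on simulated spectra.
#'
#' @param seed Integer RNG seed.
#' @param n_per_group Samples per group (default 6).
#' @param n_features Features in a simulated table (default 96).
#' @param n_markers Differential features (default 21; must be <=
#'   `n_features`).
#' @param log2_fc Log2 fold change applied to markers in the case group
#'   (default 2, i.e. 4-fold).
#' @param sigma Lognormal sd on the log2 scale (default 0.25).
#' @param ms1_ppm_noise Precursor mass jitter, ppm sd (default 2).
#' @param ms2_da_noise Fragment mass jitter, Da sd (default 0.002).
#' @param dropout Per-fragment dropout probability in `[0, 1)`.
#' @return Named list of settings.
#' @export
sim_config <- function(seed = 1, n_per_group = 6, n_features = 96,
                       n_markers = 21, log2_fc = 2, sigma = 0.25,
                       ms1_ppm_noise = 2, ms2_da_noise = 0.002,
                       dropout = 0) {
  if (n_markers > n_features) stop("n_markers exceeds n_features")
  if (dropout < 0 || dropout >= 1) stop("dropout must lie in [0, 1)")
  stopifnot(sigma >= 0, ms1_ppm_noise >= 0, ms2_da_noise >= 0)
  list(seed = as.integer(seed), n_per_group = n_per_group,
       n_features = n_features, n_markers = n_markers, log2_fc = log2_fc,
       sigma = sigma, ms1_ppm_noise = ms1_ppm_noise,
       ms2_da_noise = ms2_da_noise, dropout = dropout)
}

#' Simulate an in-silico ginsenoside MS/MS spectrum
#'
#' Builds the full sequential neutral-loss ladder of a library record:
#' the deprotonated ion (after formic-acid loss when the precursor is a
#' formate adduct), then one fragment per glycosyl residue in library
#' order (hexoses, deoxyhexoses, pentoses, hexuronic acids, malonyl),
#' terminating at the (possibly dehydrated) aglycone ion. The precursor
#' receives multiplicative ppm-scale jitter and each fragment additive
#' Da-scale jitter; fragments other than the guaranteed aglycone ion are
#' dropped with probability `dropout`. Deterministic for a fixed
#' `config$seed`.
#'
#' @param record One row of a `ginsenoside_library`.
#' @param adduct `"[M+HCOO]-"` (default) or `"[M-H]-"`.
#' @param config See [sim_config()].
#' @return List: `spectrum` (an `msms_spectrum`) and `truth` — the
#'   ground-truth class, residue counts and record name.
#' @export
simulate_spectrum <- function(record, adduct = "[M+HCOO]-",
                              config = sim_config()) {
  stopifnot(nrow(record) == 1L)
  res <- residue_table()
  rmass <- stats::setNames(res$mass, res$name)
  losses <- c(rep(rmass[["Hexose"]], record$hexose),
              rep(rmass[["Deoxyhexose"]], record$deoxyhexose),
              rep(rmass[["Pentose"]], record$pentose),
              rep(rmass[["HexuronicAcid"]], record$hexuronic_acid),
              rep(rmass[["Malonyl"]], record$malonyl))
  mass <- monoisotopic_mass(parse_formula(record$formula))
  prec_theo <- adduct_mz(mass, adduct)
  mh <- adduct_mz(mass, "[M-H]-")
  ladder <- mh - cumsum(c(0, losses))   # deprotonated ion then each loss
  with_seed(config$seed, {
    prec <- prec_theo * (1 + stats::rnorm(1, 0, config$ms1_ppm_noise) * 1e-6)
    frag <- ladder + stats::rnorm(length(ladder), 0, config$ms2_da_noise)
    keep <- stats::runif(length(frag)) >= config$dropout
    keep[length(keep)] <- TRUE          # aglycone ion always present
    frag <- frag[keep]
  })
  sp <- msms_spectrum(prec, frag, retention_time = record$rt,
                      title = record$name)
  list(spectrum = sp,
       truth = list(name = record$name, aglycone_class = record$class,
                    residue_counts = residue_counts(record[1, ])))
}

#' Simulate a two-group lognormal feature table
#'
#' Baseline log2 abundances are drawn per feature (lognormal peak
#' areas); every sample adds N(0, sigma) noise on the log2 scale; the
#' first `n_markers` features (or features named by `template`) are
#' shifted by `log2_fc` in the case group. Group labels are `"GH"`
#' (case) and `"GSW"` (reference).
#'
#' @param config See [sim_config()].
#' @param template Optional `ginsenoside_library` rows whose
#'   `"mz@rt"` strings name the marker features.
#' @return List: `table` (a `feature_table`, raw intensity scale) and
#'   `truth` — marker feature ids and the applied log2 fold change.
#' @export
make_feature_table <- function(config = sim_config(), template = NULL) {
  p <- config$n_features
  m <- config$n_markers
  n <- config$n_per_group
  feature_ids <- paste0("f", seq_len(p))
  marker_idx <- seq_len(m)
  if (!is.null(template)) {
    if (nrow(template) < m) stop("template has fewer rows than n_markers")
    mzrt <- sprintf("%.4f@%.2f",
                    ifelse(is.na(template$measured_mz), template$mz_mh,
                           template$measured_mz),
                    ifelse(is.na(template$rt), 0, template$rt))
    feature_ids[marker_idx] <- mzrt[seq_len(m)]
  }
  with_seed(config$seed, {
    base <- stats::rnorm(p, mean = 14, sd = 2)    # log2 baseline abundance
    L <- matrix(stats::rnorm(2 * n * p, 0, config$sigma), 2 * n, p)
    L <- sweep(L, 2, base, "+")
    L[seq_len(n), marker_idx] <- L[seq_len(n), marker_idx] + config$log2_fc
  })
  X <- 2^L
  tab <- feature_table(X, groups = factor(rep(c("GH", "GSW"), each = n),
                                          levels = c("GH", "GSW")),
                       sample_ids = c(paste0("GH", seq_len(n)),
                                      paste0("GSW", seq_len(n))),
                       feature_ids = feature_ids)
  list(table = tab,
       truth = list(markers = feature_ids[marker_idx],
                    log2_fc = config$log2_fc))
}

#' Simulate an interaction graph with planted hubs
#'
#' An Erdos-Renyi G(n, m) or Barabasi-Albert graph, with the members of
#' a planted clique fully interconnected: the clique members are the
#' ground-truth hubs. Deterministic for a fixed seed.
#'
#' @param n_nodes Node count.
#' @param model `"erdos_renyi"` or `"barabasi_albert"`.
#' @param n_edges Edge count for the Erdos-Renyi model (default tuned to
#'   a sparse PPI-like density).
#' @param ba_m Edges added per step for Barabasi-Albert.
#' @param clique_size Planted clique size (0 = none; must be <=
#'   `n_nodes`).
#' @param seed RNG seed.
#' @return List: `graph` (undirected simple `igraph`, nodes `g1..gn`)
#'   and `truth` — the planted hub names.
#' @export
make_graph <- function(n_nodes = 41, model = c("erdos_renyi",
                                               "barabasi_albert"),
                       n_edges = 71, ba_m = 2, clique_size = 5, seed = 1) {
  model <- match.arg(model)
  if (clique_size > n_nodes) stop("clique size exceeds node count")
  with_seed(seed, {
    g <- if (model == "erdos_renyi") {
      igraph::sample_gnm(n_nodes, min(n_edges, choose(n_nodes, 2)))
    } else {
      igraph::sample_pa(n_nodes, m = ba_m, directed = FALSE)
    }
    igraph::V(g)$name <- paste0("g", seq_len(n_nodes))
    hubs <- character(0)
    if (clique_size >= 2) {
      members <- sample(n_nodes, clique_size)
      hubs <- paste0("g", sort(members))
      pairs <- t(utils::combn(members, 2))
      g <- igraph::add_edges(g, t(pairs))
    }
    g <- igraph::simplify(g)
    list(graph = g, truth = list(hubs = hubs))
  })
}
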