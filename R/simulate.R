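#' Simulation configuration for a synthetic stimulation experiment
#'
#' Defines a desk-scale analogue of an in-vivo cytokine stimulation corpus:
#' per-condition negative-binomial counts with known planted up/down
#' signature genes. Defaults give 5 cytokines, 200 cells per condition, 400
#' genes, 20 up- and 10 down-regulated genes per cytokine at a mean planted
#' effect of 1.5 log2 units, NB dispersion 0.5, and a PBS control condition.
#'
#' @param n_cytokines number of stimulation conditions.
#' @param cells_per_condition cells per condition (control included).
#' @param n_genes genes in the panel.
#' @param n_up,n_down planted up-/down-regulated genes per cytokine.
#' @param log2fc_up,log2fc_down mean planted effect sizes (log2 units,
#'   both positive); each gene's realized effect is jittered uniformly
#'   within +/-20% of the mean.
#' @param baseline_mean_range `(low, high)` for the log-uniform draw of
#'   per-gene baseline NB means.
#' @param dispersion NB dispersion `phi` (variance `mu + phi mu^2`).
#' @param overlap_fraction fraction of each cytokine's planted genes shared
#'   with the previous cytokine's, mimicking functionally redundant
#'   signatures. In `[0, 1]`.
#' @param include_control add an unperturbed `"PBS"` condition.
#' @param seed integer seed; generation is fully reproducible.
#'
#' @return list of class `SimulationConfig`.
#' @export
simulation_config <- function(n_cytokines = 5L, cells_per_condition = 200L,
                              n_genes = 400L, n_up = 20L, n_down = 10L,
                              log2fc_up = 1.5, log2fc_down = 1.5,
                              baseline_mean_range = c(0.25, 8),
                              dispersion = 0.5, overlap_fraction = 0,
                              include_control = TRUE, seed = 1L) {
  cfg <- list(n_cytokines = as.integer(n_cytokines),
              cells_per_condition = as.integer(cells_per_condition),
              n_genes = as.integer(n_genes),
              n_up = as.integer(n_up), n_down = as.integer(n_down),
              log2fc_up = log2fc_up, log2fc_down = log2fc_down,
              baseline_mean_range = baseline_mean_range,
              dispersion = dispersion,
              overlap_fraction = overlap_fraction,
              include_control = isTRUE(include_control),
              seed = as.integer(seed))
  with(cfg, {
    if (n_cytokines < 1L || cells_per_condition < 1L || n_genes < 1L ||
        n_up < 0L || n_down < 0L) {
      stop("all counts in the simulation config must be positive")
    }
    if (n_up + n_down > n_genes) stop("n_up + n_down must be <= n_genes")
    if (log2fc_up < 0 || log2fc_down < 0) {
      stop("planted effect sizes must be non-negative")
    }
    if (length(baseline_mean_range) != 2L ||
        any(baseline_mean_range <= 0) ||
        baseline_mean_range[1] > baseline_mean_range[2]) {
      stop("baseline_mean_range must be (low, high) with 0 < low <= high")
    }
    if (dispersion <= 0) stop("dispersion must be positive")
    if (overlap_fraction < 0 || overlap_fraction > 1) {
      stop("overlap_fraction must lie in [0, 1]")
    }
  })
  structure(cfg, class = "SimulationConfig")
}

#' Simulate a cytokine stimulation experiment with planted signatures
#'
#' Per gene, a baseline mean is drawn log-uniformly from
#' `baseline_mean_range`; counts come from a negative binomial with the
#' configured dispersion. For cells of condition `k`, the planted up genes'
#' means are multiplied by `2^effect` and the down genes' by `2^-effect`,
#' with per-gene effects jittered uniformly within +/-20% of the configured
#' means. Control cells (label `"PBS"`) are unperturbed. Consecutive
#' cytokines share `overlap_fraction` of their planted genes.
#'
#' @param config a [simulation_config()].
#' @return list with `counts` (cells x genes integer matrix), `labels`
#'   (per-cell condition), and `truth`: per-cytokine data frames of planted
#'   genes with signed realized effects, plus `cytokine_to_gene`, a
#'   ligand-proxy map from each cytokine to its first planted up gene.
#' @export
simulate_stimulation_experiment <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  cfg <- config
  with_seed(cfg$seed, {
    genes <- sprintf("gene%04d", seq_len(cfg$n_genes))
    cytokines <- sprintf("CK%02d", seq_len(cfg$n_cytokines))
    conditions <- c(cytokines, if (cfg$include_control) "PBS")
    lo <- log(cfg$baseline_mean_range[1])
    hi <- log(cfg$baseline_mean_range[2])
    baseline <- exp(runif(cfg$n_genes, lo, hi))

    # allocate planted gene indices; cytokine k shares a prefix of its
    # planted genes with cytokine k-1 when overlap_fraction > 0
    n_sig <- cfg$n_up + cfg$n_down
    truth <- list()
    planted <- vector("list", cfg$n_cytokines)
    pool <- sample.int(cfg$n_genes)    # randomized allocation order
    cursor <- 1L
    take <- function(n) {
      if (cursor + n - 1L > length(pool)) {
        stop("not enough genes to plant disjoint signatures; ",
             "increase n_genes or overlap_fraction")
      }
      out <- pool[cursor:(cursor + n - 1L)]
      cursor <<- cursor + n
      out
    }
    for (k in seq_len(cfg$n_cytokines)) {
      n_shared <- if (k > 1L) round(cfg$overlap_fraction * n_sig) else 0L
      shared <- if (n_shared > 0L) {
        prev <- planted[[k - 1L]]
        prev$idx[seq_len(min(n_shared, length(prev$idx)))]
      } else integer(0)
      fresh <- take(n_sig - length(shared))
      idx <- c(shared, fresh)
      up <- idx[seq_len(cfg$n_up)]
      dn <- if (cfg$n_down > 0L) idx[cfg$n_up + seq_len(cfg$n_down)] else
        integer(0)
      eff_up <- cfg$log2fc_up * runif(length(up), 0.8, 1.2)
      eff_dn <- cfg$log2fc_down * runif(length(dn), 0.8, 1.2)
      planted[[k]] <- list(idx = idx, up = up, dn = dn,
                           eff_up = eff_up, eff_dn = eff_dn)
      truth[[cytokines[k]]] <- data.frame(
        gene = genes[c(up, dn)],
        direction = rep(c("up", "down"), c(length(up), length(dn))),
        log2fc = c(eff_up, -eff_dn),
        stringsAsFactors = FALSE)
    }

    n_cond <- length(conditions)
    n_cells <- n_cond * cfg$cells_per_condition
    labels <- rep(conditions, each = cfg$cells_per_condition)
    counts <- matrix(0L, nrow = n_cells, ncol = cfg$n_genes,
                     dimnames = list(sprintf("cell%05d", seq_len(n_cells)),
                                     genes))
    size <- 1 / cfg$dispersion
    for (ci in seq_len(n_cond)) {
      mu <- baseline
      if (conditions[ci] != "PBS") {
        pk <- planted[[ci]]
        mu[pk$up] <- mu[pk$up] * 2^pk$eff_up
        if (length(pk$dn)) mu[pk$dn] <- mu[pk$dn] * 2^(-pk$eff_dn)
      }
      rows <- (ci - 1L) * cfg$cells_per_condition +
        seq_len(cfg$cells_per_condition)
      counts[rows, ] <- matrix(
        rnbinom(length(rows) * cfg$n_genes, mu = rep(mu, each = length(rows)),
                size = size),
        nrow = length(rows))
    }
    cytokine_to_gene <- setNames(
      lapply(planted, function(pk) genes[pk$up[1L]]), cytokines)
    list(counts = counts, labels = labels, truth = truth,
         cytokine_to_gene = cytokine_to_gene, baseline_mean = baseline)
  })
}

#' End-to-end parameter recovery on simulated data
#'
#' The package's self-validation harness: simulate a stimulation
#' experiment, log-normalize, hold out one stratified fold, build
#' signatures on the training cells, score the held-out cells with
#' [mousse()] and return the per-cytokine one-vs-rest AUC-ROC.
#'
#' @param config a [simulation_config()].
#' @param num_genes,alpha,control_label passed to [build_signatures()]
#'   (`control_label` defaults to `"PBS"` when the config includes the
#'   control). Setting `alpha = 1` disables the significance filter, which
#'   keeps signatures (and hence scores) defined under a null simulation
#'   with zero planted effects.
#' @param k folds for the stratified split; fold 1 is held out.
#' @param component,tech_method,use_weights passed to [mousse()].
#'
#' @return Named numeric vector of per-cytokine held-out AUC-ROC values.
#' @export
end_to_end_recovery <- function(config, num_genes = 60L, alpha = 0.05,
                                control_label = NULL, k = 5L,
                                component = "combined",
                                tech_method = "trend_fit",
                                use_weights = TRUE) {
  stopifnot(is(config, "SimulationConfig"), config$n_cytokines >= 2L)
  sim <- simulate_stimulation_experiment(config)
  expr <- log_normalize(sim$counts)
  labels <- sim$labels[rownames(sim$counts) %in% rownames(expr)]
  if (is.null(control_label) && config$include_control) {
    control_label <- "PBS"
  }
  folds <- stratified_kfold(labels, k = k, seed = config$seed)
  train <- folds != 1L
  sig <- suppressWarnings(build_signatures(
    labeled_dataset(expr[train, , drop = FALSE], labels[train]),
    num_genes = num_genes, alpha = alpha, control_label = control_label))
  nonempty <- vapply(sig$sets, function(p) {
    length(p$positive) + length(p$negative) > 0L
  }, logical(1))
  if (!any(nonempty)) {
    return(setNames(rep(NA_real_, length(sig$sets)), names(sig$sets)))
  }
  sm <- mousse(expr[!train, , drop = FALSE], sig, component = component,
               tech_method = tech_method, use_weights = use_weights)
  test_labels <- labels[!train]
  cytokines <- setdiff(sort(unique(labels)), control_label)
  setNames(vapply(cytokines, function(cy) {
    if (!cy %in% colnames(sm$values)) return(NA_real_)
    roc_auc_ovr(sm$values[, cy], test_labels == cy)
  }, numeric(1)), cytokines)
}
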