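# Small panels and pools used across test files. Everything is generated in
# code at test time; sizes are kept small so the whole suite stays fast.

small_panel <- function(seed = 7, n_landmark = 16, n_drugs = 4, n_genes = 10,
                        ...) {
  simulate_panel(panel_config(
    n_landmark = n_landmark, n_drugs = n_drugs, n_genes = n_genes,
    targets_per_drug = c(1, 2), trials_per_entity = c(1, 8),
    signal_strength = 2, trial_noise_sd = 0.5, outlier_fraction = 0.1,
    seed = seed, ...
  ))
}

small_pool <- function(seed = 7, ratio = 2) {
  panel <- small_panel(seed)
  dc <- aggregate_profiles(panel$drug_trials, seed = seed + 1)
  gc_ <- aggregate_profiles(panel$gene_trials, seed = seed + 2)
  build_sample_pool(dc, gc_, panel$truth_edges, ratio = ratio)
}

# random TrialSet matrix: a coherent cluster plus optional pure-noise rows
random_trialset <- function(n_coherent, n_noise, n_features = 12, seed = 1) {
  withr::with_seed(seed, {
    center <- rnorm(n_features, sd = 2)
    coherent <- matrix(rnorm(n_coherent * n_features, sd = 0.3),
                       nrow = n_coherent, byrow = TRUE) +
      matrix(center, nrow = n_coherent, ncol = n_features, byrow = TRUE)
    noise <- matrix(rnorm(n_noise * n_features, sd = 2),
                    nrow = n_noise, ncol = n_features)
    rbind(coherent, noise)
  })
}

# independent scalar re-implementation of the penalized objective, written
# as plain loops so it shares no code with penalized_loss()
loss_oracle <- function(prob, labels, eta, eps = 1e-7) {
  total <- 0
  for (i in seq_along(labels)) {
    p1 <- min(max(prob[i, 2], eps), 1 - eps)
    if (labels[i] == 1) {
      total <- total - log(p1)
    } else {
      total <- total - log(1 - p1) - eta * abs(prob[i, 1])
    }
  }
  unname(total / length(labels))
}

# exhaustive selection oracle over a produced partition: best mean
# intra-cluster correlation among clusters with replicate support
oracle_winner <- function(m, cluster) {
  labs <- sort(unique(cluster))
  icc <- vapply(labs, function(cl) {
    intra_class_correlation(m, which(cluster == cl))
  }, numeric(1))
  eligible <- which(tabulate(cluster, max(labs)) [labs] >= 2)
  if (length(eligible) == 0) eligible <- seq_along(labs)
  labs[eligible][which.max(icc[eligible])]
}

# flatten / restore network parameters for numerical gradient checks
flatten_params <- function(params) {
  unlist(c(lapply(params$weights, as.numeric),
           lapply(params$biases, as.numeric)))
}

unflatten_params <- function(theta, template) {
  out <- template
  pos <- 0L
  for (l in seq_along(template$weights)) {
    k <- length(template$weights[[l]])
    out$weights[[l]] <- matrix(theta[pos + seq_len(k)],
                               nrow = nrow(template$weights[[l]]))
    pos <- pos + k
  }
  for (l in seq_along(template$biases)) {
    k <- length(template$biases[[l]])
    out$biases[[l]] <- theta[pos + seq_len(k)]
    pos <- pos + k
  }
  out
}
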