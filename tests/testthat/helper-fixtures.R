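# Shared fixtures: a standard synthetic AIF and small phantoms, built in
# code so every test regenerates them deterministically.

std_times <- seq(0, 59, by = 1)

std_aif <- function(hematocrit = 0.42, times = std_times) {
  gamma_variate_aif(aif_model_params(), times, hematocrit = hematocrit)
}

# Single-slice phantom small enough for per-pixel fitting in tests.
small_phantom <- function(model = "tofts", noise_sd = 0, seed = 1L,
                          stress = seq(1.0, 4.0, length.out = 16),
                          rest = rep(1.2, 16)) {
  make_phantom(phantom_spec(
    dim = c(32, 32), pixdim = 2, n_slices = 1,
    sector_truth = list(stress = stats::setNames(stress, 1:16),
                        rest = stats::setNames(rest, 1:16)),
    model = model, noise_sd = noise_sd, seed = seed))
}

# Peak myocardial concentration of a noise-free phantom (for SNR scaling).
phantom_peak_conc <- function(ph) {
  max(ph$stress$data[rep(as.vector(ph$mask), length(ph$stress$times))])
}

# Independent AUC: exhaustive pairwise comparison count.
auc_bruteforce <- function(scores, labels, direction = "lower") {
  s <- if (direction == "lower") -scores else scores
  pos <- s[as.logical(labels)]; neg <- s[!as.logical(labels)]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# Independent ICC(A,1): mean squares from stats::aov on the long layout.
icc_a1_aov <- function(x, y) {
  n <- length(x)
  df <- data.frame(v = c(x, y), subj = factor(rep(seq_len(n), 2)),
                   rater = factor(rep(1:2, each = n)))
  a <- stats::anova(stats::aov(v ~ subj + rater, data = df))
  msr <- a["subj", "Mean Sq"]; msc <- a["rater", "Mean Sq"]
  mse <- a["Residuals", "Mean Sq"]
  (msr - mse) / (msr + mse + 2 * (msc - mse) / n)
}
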