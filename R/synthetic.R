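# Synthetic reference pools and model samples with known ground truth.
#
# Archetypes emulate the distribution shapes seen across real probesets:
# silent (unimodal low), housekeeping (unimodal high), bimodal (low in some
# cell types, high in others), ramp (evenly spread), and noisy_unimodal
# (wide single mode, the "noisy probeset" shape). Defaults put the low and
# high modes at 4 and 10 log2 units with sd 0.5, sitting inside the 1-10
# log2 spread of dynamic ranges seen on real platforms.

.archetype_kinds <- c("silent", "housekeeping", "bimodal", "ramp",
                      "noisy_unimodal")

# deterministic per-index seed streams: adding probesets never perturbs
# existing rows, and the archetype assignment below is independent of the
# total number of probesets
.derive_seed <- function(master, i) {
  as.integer((as.double(master %% 1000003L) + 1000003 * i) %% 2147483629)
}

# low-discrepancy archetype assignment: index i gets the archetype whose
# cumulative mix interval contains frac(i * golden ratio)
.assign_archetypes <- function(n, mix) {
  u <- (seq_len(n) * 0.618033988749895) %% 1
  cs <- cumsum(mix)
  names(mix)[findInterval(u, cs[-length(cs)]) + 1L]
}

#' Generate a synthetic reference pool with ground truth
#'
#' Emits a probesets x samples log2 expression matrix in which each probeset
#' row is drawn from one of five distribution archetypes, together with the
#' generating truth (archetype per probeset, true threshold where defined,
#' and the true low/high state of every sample for bimodal probesets). The
#' generator is a pure function of its arguments and the seed; each probeset
#' has its own derived random stream, so enlarging the pool by adding
#' probesets never changes existing rows.
#'
#' @param n_samples Number of arrays (columns), >= 2.
#' @param n_probesets Number of probesets (rows).
#' @param mix Named archetype fractions summing to 1; names among
#'   `silent`, `housekeeping`, `bimodal`, `ramp`, `noisy_unimodal`.
#' @param seed Master seed.
#' @param mu_low,mu_high Low/high mode centers, log2 scale (defaults 4, 10).
#' @param sigma Mode sd for silent/housekeeping/bimodal (default 0.5).
#' @param sigma_wide Sd of the wide unimodal archetype (default 1.5).
#' @param p_high Probability a bimodal sample sits in the high component.
#' @return A list with `matrix` (rownames `ps_*`, colnames `s_*`) and
#'   `truth`: a list with `table` (data.frame: probeset_id, archetype,
#'   true_threshold), `states` (named list of logical high-state vectors for
#'   bimodal probesets) and `params`.
#' @examples
#' pool <- generate_reference_pool(20, 10, seed = 42)
#' table(pool$truth$table$archetype)
#' @export
generate_reference_pool <- function(n_samples, n_probesets,
                                    mix = c(silent = 0.4, housekeeping = 0.3,
                                            bimodal = 0.2,
                                            noisy_unimodal = 0.1),
                                    seed = 1,
                                    mu_low = 4, mu_high = 10,
                                    sigma = 0.5, sigma_wide = 1.5,
                                    p_high = 0.5) {
  if (n_samples < 2) stop("n_samples must be >= 2")
  if (n_probesets < 1) stop("n_probesets must be >= 1")
  if (is.null(names(mix)) || !all(names(mix) %in% .archetype_kinds))
    stop("mix names must be among: ", paste(.archetype_kinds, collapse = ", "))
  if (any(mix < 0) || abs(sum(mix) - 1) > 1e-8)
    stop("mix fractions must be non-negative and sum to 1")
  if (!(mu_low < mu_high)) stop("mu_low must be below mu_high")
  if (sigma <= 0 || sigma_wide <= 0) stop("sigma values must be positive")
  if (!(p_high > 0 && p_high < 1)) stop("p_high must lie in (0, 1)")

  arch <- .assign_archetypes(n_probesets, mix)
  ids <- sprintf("ps_%0*d", max(4L, nchar(n_probesets)), seq_len(n_probesets))
  mid <- (mu_low + mu_high) / 2

  mat <- matrix(NA_real_, n_probesets, n_samples,
                dimnames = list(ids, sprintf("s_%04d", seq_len(n_samples))))
  states <- list()
  for (i in seq_len(n_probesets)) {
    set.seed(.derive_seed(seed, i))
    row <- switch(arch[i],
      silent = stats::rnorm(n_samples, mu_low, sigma),
      housekeeping = stats::rnorm(n_samples, mu_high, sigma),
      bimodal = {
        hi <- stats::runif(n_samples) < p_high
        states[[ids[i]]] <- hi
        stats::rnorm(n_samples, ifelse(hi, mu_high, mu_low), sigma)
      },
      ramp = stats::runif(n_samples, mu_low, mu_high),
      noisy_unimodal = stats::rnorm(n_samples, mid, sigma_wide))
    mat[i, ] <- row
  }

  truth <- list(
    table = data.frame(
      probeset_id = ids,
      archetype = arch,
      true_threshold = ifelse(arch %in% c("bimodal", "ramp"), mid, NA_real_),
      stringsAsFactors = FALSE),
    states = states,
    params = list(mu_low = mu_low, mu_high = mu_high, sigma = sigma,
                  sigma_wide = sigma_wide, p_high = p_high, seed = seed,
                  mix = as.list(mix))
  )
  list(matrix = mat, truth = truth)
}

# stable small polynomial hash of a string, for name-keyed random streams
.name_hash <- function(s) {
  v <- utf8ToInt(s)
  h <- 0
  for (ch in v) h <- (h * 131 + ch) %% 2147480009
  as.integer(h)
}

#' Generate replicate model samples from planted population states
#'
#' Given a planted truth — for every population and probeset, whether the
#' probeset is LOW or HIGH in that population — draws `n_replicates`
#' normalized arrays per population with values
#' `N(mu_state, sigma_noise^2)`. Each population's random stream is keyed by
#' its name, so permuting population order (or adding populations) permutes
#' or extends the output without disturbing other populations.
#'
#' @param states Character matrix, probesets x populations, entries
#'   `"LOW"`/`"HIGH"`; rownames probeset ids, colnames population names.
#' @param n_replicates Replicates per population (default 3).
#' @param sigma_noise Replicate noise sd; 0 yields exactly the state means.
#' @param mu_low,mu_high State means, log2 scale.
#' @param seed Master seed.
#' @return A list with `matrix` (probesets x populations*replicates, column
#'   names `<population>.<replicate>`), `populations` (named list mapping
#'   population to its column names) and `truth` (the states matrix).
#' @export
generate_model_samples <- function(states, n_replicates = 3,
                                   sigma_noise = 0.5,
                                   mu_low = 4, mu_high = 10, seed = 1) {
  if (!is.matrix(states) || is.null(rownames(states)) ||
      is.null(colnames(states)))
    stop("states must be a character matrix with probeset rownames and ",
         "population colnames")
  if (!all(states %in% c("LOW", "HIGH")))
    stop("undefined state: entries must be \"LOW\" or \"HIGH\"")
  if (sigma_noise < 0) stop("sigma_noise must be >= 0")
  pops <- colnames(states)
  nps <- nrow(states)
  cols <- list()
  for (p in pops) {
    set.seed((.name_hash(p) + seed) %% 2147480009)
    mu <- ifelse(states[, p] == "HIGH", mu_high, mu_low)
    reps <- matrix(stats::rnorm(nps * n_replicates, mean = mu,
                                sd = sigma_noise),
                   nps, n_replicates)
    colnames(reps) <- paste0(p, ".", seq_len(n_replicates))
    cols[[p]] <- reps
  }
  mat <- do.call(cbind, cols)
  rownames(mat) <- rownames(states)
  list(matrix = mat,
       populations = lapply(cols, colnames),
       truth = states)
}

#' Write generator ground truth as JSON
#'
#' @param truth The `truth` element of [generate_reference_pool()].
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
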