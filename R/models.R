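# Populations (replicate averaging), models (population collections),
# expression-pattern search and activity summaries.

#' Define a population of biological replicates
#'
#' A population is a set of replicate arrays of one purified cell type,
#' identified by the sample ids (columns) holding its replicates, plus
#' free-form metadata (organ, strain, age, sex, ...).
#'
#' @param name Population name (unique within a model).
#' @param sample_ids Character vector of replicate sample ids (>= 1).
#' @param metadata Named list of free-form descriptors.
#' @return An object of class `"population"`.
#' @export
population <- function(name, sample_ids, metadata = list()) {
  if (!nzchar(name)) stop("population name must be non-empty")
  if (length(sample_ids) < 1) stop("a population needs at least 1 replicate")
  structure(list(name = name, sample_ids = as.character(sample_ids),
                 metadata = metadata),
            class = "population")
}

#' Average replicates and map a population onto the reference
#'
#' Replicate arrays are normalized individually (upstream), averaged per
#' probeset, and the averaged values are mapped onto the probeset
#' meta-profiles. Averaging precedes mapping, so a population's percentile
#' is the percentile of its mean intensity, not the mean of replicate
#' percentiles.
#'
#' @param samples Numeric matrix (probesets x replicates) of normalized
#'   log2 intensities, or a single named vector.
#' @param reference A `"common_reference"`.
#' @param name Population name.
#' @param metadata Named list of descriptors.
#' @param band_cut,method Passed to [map_sample()].
#' @return A `"population_profile"`: list with `name`, `n_replicates`,
#'   `mean_intensity`, `activity` (an activity profile of the averages) and
#'   `reference_version`.
#' @export
build_population_profile <- function(samples, reference, name = "population",
                                     metadata = list(), band_cut = 50,
                                     method = c("rank", "linear")) {
  stopifnot(inherits(reference, "common_reference"))
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1,
                                            dimnames = list(names(samples)))
  if (ncol(samples) < 1) stop("a population needs at least 1 replicate")
  avg <- rowMeans(samples)
  names(avg) <- rownames(samples)
  act <- map_sample(avg, reference, band_cut = band_cut, method = method,
                    id = name)
  structure(
    list(name = name,
         n_replicates = ncol(samples),
         metadata = metadata,
         mean_intensity = avg,
         activity = act,
         reference_version = attr(act, "reference_version")),
    class = "population_profile"
  )
}

#' Assemble population profiles into a model
#'
#' A model is a named collection of population profiles, all mapped against
#' the same common-reference version, over which expression patterns can be
#' searched. Optional 2-D layout coordinates per population are stored for
#' display only.
#'
#' @param name Model name.
#' @param profiles List of `"population_profile"` objects.
#' @param reference The `"common_reference"` the profiles were mapped
#'   against (supplies the trimmed dynamic ranges used to sort search hits).
#' @param layout Optional data.frame with columns `population`, `x`, `y`.
#' @return An object of class `"expression_model"`.
#' @export
expression_model <- function(name, profiles, reference, layout = NULL) {
  stopifnot(inherits(reference, "common_reference"))
  if (!length(profiles)) stop("a model needs at least one population")
  ok <- vapply(profiles, inherits, logical(1), "population_profile")
  if (!all(ok)) stop("profiles must be population_profile objects")
  pnames <- vapply(profiles, `[[`, character(1), "name")
  if (anyDuplicated(pnames))
    stop("duplicate population names: ",
         paste(unique(pnames[duplicated(pnames)]), collapse = ", "))
  versions <- vapply(profiles, `[[`, character(1), "reference_version")
  if (length(unique(versions)) != 1L)
    stop("populations were mapped against different reference versions: ",
         paste(unique(versions), collapse = ", "))
  if (!identical(unique(versions), reference$version))
    stop("profiles were mapped against ", unique(versions),
         " but the supplied reference is ", reference$version)
  names(profiles) <- pnames
  structure(
    list(name = name,
         populations = pnames,
         profiles = profiles,
         probeset_ids = reference$probeset_ids,
         dynamic_ranges = reference_dynamic_ranges(reference, trimmed = TRUE),
         reference_version = reference$version,
         layout = layout),
    class = "expression_model"
  )
}

# probesets x populations character matrix of calls or bands
.model_table <- function(model, what = c("call", "band")) {
  what <- match.arg(what)
  tab <- sapply(model$profiles, function(p) p$activity[[what]])
  if (is.null(dim(tab)))
    tab <- matrix(tab, nrow = 1, dimnames = list(NULL, model$populations))
  tab
}

# probesets x populations percentile matrix
.model_percentiles <- function(model) {
  perc <- sapply(model$profiles, function(p) p$activity$percentile)
  if (is.null(dim(perc)))
    perc <- matrix(perc, nrow = 1, dimnames = list(NULL, model$populations))
  perc
}

#' Search a model for probesets matching a high/low pattern
#'
#' A probeset matches when, for every constrained population, its
#' replicate-averaged call equals the constraint; `any` matches always.
#' Hits are sorted by trimmed dynamic range, greatest first (the most
#' informative probesets lead), ties broken by probeset id.
#'
#' @param model An `"expression_model"`.
#' @param pattern Named character vector or list, population ->
#'   `"high"`/`"low"`/`"any"` (case-insensitive). Unnamed populations count
#'   as `any`.
#' @return A data.frame with `probeset_id`, `trimmed_dynamic_range` and one
#'   call column per population, sorted as described.
#' @examples
#' # see vignette("absolute-expression-profiling") for an end-to-end model
#' @export
pattern_search <- function(model, pattern) {
  stopifnot(inherits(model, "expression_model"))
  pattern <- unlist(pattern)
  unknown <- setdiff(names(pattern), model$populations)
  if (length(unknown))
    stop("unknown population name(s): ", paste(unknown, collapse = ", "))
  constraint <- toupper(pattern)
  if (!all(constraint %in% c("HIGH", "LOW", "ANY")))
    stop("pattern values must be high, low or any")
  calls <- .model_table(model, "call")
  keep <- rep(TRUE, nrow(calls))
  for (p in names(constraint)) {
    if (constraint[[p]] == "ANY") next
    keep <- keep & calls[, p] == constraint[[p]]
  }
  ids <- model$probeset_ids[keep]
  dr <- model$dynamic_ranges[keep]
  ord <- order(-dr, ids)
  out <- data.frame(probeset_id = ids[ord],
                    trimmed_dynamic_range = unname(dr[ord]),
                    calls[keep, , drop = FALSE][ord, , drop = FALSE],
                    row.names = NULL, check.names = FALSE,
                    stringsAsFactors = FALSE)
  out
}

#' Summarize probeset activity across all populations of a model
#'
#' Reduces each probeset over the model's populations into one of five
#' disjoint categories: `always_very_high` (band VERY_HIGH in every
#' population), `always_high` (call HIGH everywhere, but not very-high
#' everywhere), `always_low` / `always_very_low` (mirrored), and `dynamic`
#' (high in some populations, low in others). The five counts partition the
#' probesets.
#'
#' @param model An `"expression_model"`.
#' @param band_cut Percentile cut defining the very-high/very-low bands
#'   (default 50); applied to the stored population percentiles.
#' @return A list with `counts` (named integer vector over the five
#'   categories) and `category` (named character vector per probeset).
#' @export
activity_summary <- function(model, band_cut = 50) {
  stopifnot(inherits(model, "expression_model"))
  calls <- .model_table(model, "call")
  perc <- .model_percentiles(model)
  all_high <- apply(calls == "HIGH", 1, all)
  all_low <- apply(calls == "LOW", 1, all)
  all_vhigh <- all_high & apply(perc >= band_cut, 1, all)
  all_vlow <- all_low & apply(perc <= -band_cut, 1, all)
  category <- ifelse(all_vhigh, "always_very_high",
              ifelse(all_high, "always_high",
              ifelse(all_vlow, "always_very_low",
              ifelse(all_low, "always_low", "dynamic"))))
  names(category) <- model$probeset_ids
  lev <- c("always_very_high", "always_high", "always_low",
           "always_very_low", "dynamic")
  counts <- table(factor(category, levels = lev))
  list(counts = stats::setNames(as.integer(counts), lev),
       category = category)
}

#' Probesets specific to one population
#'
#' `high_only` are probesets called HIGH in the named population and LOW in
#' every other population; `low_only` is the mirror. With `use_bands = TRUE`
#' the stricter very-high/very-low bands are required instead of the binary
#' calls.
#'
#' @param model An `"expression_model"`.
#' @param population Population name.
#' @param band_cut Percentile cut for the band-based variant.
#' @param use_bands Require VERY_HIGH/VERY_LOW instead of HIGH/LOW?
#' @return A list with character vectors `high_only` and `low_only`.
#' @export
population_specific <- function(model, population, band_cut = 50,
                                use_bands = FALSE) {
  stopifnot(inherits(model, "expression_model"))
  if (!population %in% model$populations)
    stop("unknown population: ", population)
  calls <- .model_table(model, "call")
  if (use_bands) {
    perc <- .model_percentiles(model)
    hi <- perc >= band_cut
    lo <- perc <= -band_cut
  } else {
    hi <- calls == "HIGH"
    lo <- calls == "LOW"
  }
  others <- setdiff(model$populations, population)
  all_other_low <- if (length(others))
    apply(lo[, others, drop = FALSE], 1, all) else rep(TRUE, nrow(calls))
  all_other_high <- if (length(others))
    apply(hi[, others, drop = FALSE], 1, all) else rep(TRUE, nrow(calls))
  list(high_only = model$probeset_ids[hi[, population] & all_other_low],
       low_only = model$probeset_ids[lo[, population] & all_other_high])
}

#' Rank a gene's probesets by trimmed dynamic range
#'
#' When a platform carries several probesets for one gene, the probeset with
#' the largest trimmed dynamic range is the most informative; this orders a
#' user-supplied gene-to-probeset mapping accordingly (ties broken by id).
#'
#' @param mapping Data.frame with columns `gene` and `probeset_id`, or a
#'   character vector of probeset ids.
#' @param reference A `"common_reference"`.
#' @param gene Optional gene to filter the mapping to.
#' @return Character vector of probeset ids, greatest trimmed dynamic range
#'   first.
#' @export
rank_probesets_for_gene <- function(mapping, reference, gene = NULL) {
  stopifnot(inherits(reference, "common_reference"))
  if (is.data.frame(mapping)) {
    if (!all(c("gene", "probeset_id") %in% names(mapping)))
      stop("mapping needs columns gene and probeset_id")
    if (!is.null(gene)) mapping <- mapping[mapping$gene == gene, , drop = FALSE]
    ids <- as.character(mapping$probeset_id)
  } else {
    ids <- as.character(mapping)
  }
  missing_ids <- setdiff(ids, reference$probeset_ids)
  if (length(missing_ids))
    stop("probeset(s) absent from the reference: ",
         paste(missing_ids, collapse = ", "))
  dr <- reference_dynamic_ranges(reference, trimmed = TRUE)[ids]
  ids[order(-dr, ids)]
}

#' @export
print.expression_model <- function(x, ...) {
  cat("Expression model \"", x$name, "\": ", length(x$populations),
      " populations x ", length(x$probeset_ids), " probesets (reference ",
      x$reference_version, ")\n", sep = "")
  cat("  populations:", paste(x$populations, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.population_profile <- function(x, ...) {
  cat("Population profile \"", x$name, "\" (", x$n_replicates,
      " replicates, reference ", x$reference_version, ")\n", sep = "")
  print(table(x$activity$band))
  invisible(x)
}
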