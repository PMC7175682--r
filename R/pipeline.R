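#' Run the full diet-analysis pipeline
#'
#' Orchestrates the stages end to end: validate, exclude minor constituents,
#' weight by load size, aggregate per bee species, classify host range for
#' species with at least `cfg$min_loads` loads, rarefy diet breadth in two
#' tiers (species with >= 10 loads to 12 loads, species with >= 3 loads to 3
#' loads; a species additionally needs pooled units >= target x 10), and —
#' when an occurrence table is supplied — fit the breadth--occurrence model
#' on the upper tier (Gaussian linear model, bee family as a fixed factor
#' when `bee_families` is given) and a Spearman rank correlation on the
#' lower tier. Exclusions at every stage are recorded. When `out_dir` is
#' given, writes `profiles.csv`, `classification.csv`, `rarefaction.csv`,
#' `stats.json` and a reproducibility `manifest.json`.
#'
#' @param loads a `pollen_loads` (or a path to a loads CSV).
#' @param taxonomy a `pollen_taxonomy` (or a path to a taxonomy CSV).
#' @param occurrence optional `occurrence_table` (or path).
#' @param cfg a `lecty_config`.
#' @param tiers named integer vector of rarefaction tiers: minimum loads ->
#'   target loads (default `c("10" = 12, "3" = 3)`).
#' @param n_resamples Monte-Carlo resamples per species (default 1000).
#' @param seed integer seed for the rarefaction resampling.
#' @param minor_threshold percent threshold for the constituent filter.
#' @param bee_families optional named character vector mapping bee species
#'   to bee family (enables the bee-family fixed factor).
#' @param out_dir optional output directory.
#' @return A `pollen_pipeline` list: `profiles`, `profiles_table`,
#'   `classification`, `rarefaction` (one data.frame per tier),
#'   `stats`, `exclusions`, `manifest`.
#' @export
run_pipeline <- function(loads, taxonomy, occurrence = NULL,
                         cfg = lecty_config(), tiers = c("10" = 12, "3" = 3),
                         n_resamples = 1000, seed = 1L,
                         minor_threshold = 1.0, bee_families = NULL,
                         out_dir = NULL) {
  input_digests <- list()
  if (is.character(taxonomy)) {
    input_digests$taxonomy <- unname(tools::md5sum(taxonomy))
    taxonomy <- read_taxonomy(taxonomy)
  }
  if (is.character(loads)) {
    input_digests$loads <- unname(tools::md5sum(loads))
    loads <- read_loads(loads, taxonomy)
  } else {
    loads <- pollen_loads(as.data.frame(loads), taxonomy)
  }
  if (is.character(occurrence)) {
    input_digests$occurrence <- unname(tools::md5sum(occurrence))
    occurrence <- read_occurrence(occurrence)
  }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  filtered <- stage("filter", filter_minor_constituents(loads,
                                                        minor_threshold))
  weighted <- stage("weight", weight_load(filtered))
  profiles <- stage("aggregate", aggregate_profiles(weighted, taxonomy))

  classification <- stage("classify", classify_table(profiles, cfg))
  exclusions <- list(classification = attr(classification, "excluded"))

  rarefaction <- list()
  for (nm in names(tiers)) {
    min_loads <- as.integer(nm)
    target <- tiers[[nm]]
    eligible <- Filter(function(p) p$n_loads >= min_loads, profiles)
    tier <- stage("rarefy",
                  rarefy_profiles(eligible, target, n_resamples, seed))
    key <- paste0("min", min_loads, "_to", target)
    rarefaction[[key]] <- tier
    exclusions[[paste0("rarefaction_", key)]] <- c(
      setdiff(names(profiles), names(eligible)), attr(tier, "excluded"))
  }

  stats_out <- list()
  if (!is.null(occurrence) && length(rarefaction) > 0) {
    breadth_tables <- lapply(rarefaction, function(tier) {
      if (nrow(tier) == 0) return(NULL)
      df <- data.frame(
        bee_species = tier$bee_species,
        rarefied_breadth = tier$expected_richness,
        n_farms = vapply(tier$bee_species,
                         function(b) farm_occurrence(occurrence, b),
                         numeric(1)),
        stringsAsFactors = FALSE)
      if (!is.null(bee_families)) {
        df$bee_family <- unname(bee_families[df$bee_species])
      }
      df
    })
    upper <- breadth_tables[[1]]
    if (!is.null(upper) && nrow(upper) >= 3 &&
        length(unique(upper$rarefied_breadth)) > 1) {
      use_family <- !is.null(bee_families) &&
        length(unique(upper$bee_family)) > 1
      fit <- stage("stats",
                   gaussian_linear_fit(upper,
                                       include_bee_family = use_family))
      stats_out$linear_model <- list(
        tier = names(rarefaction)[1], formula = fit$formula,
        coefficients = fit$coefficients,
        adj_r_squared = fit$adj_r_squared, n = nrow(upper))
    }
    if (length(breadth_tables) >= 2) {
      lower <- breadth_tables[[length(breadth_tables)]]
      if (!is.null(lower) && nrow(lower) >= 3 &&
          length(unique(lower$rarefied_breadth)) > 1 &&
          length(unique(lower$n_farms)) > 1) {
        sp <- stage("stats", spearman_rank(lower))
        stats_out$spearman <- c(tier = names(rarefaction)[length(rarefaction)],
                                sp)
      }
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("pollendiet")),
    input_digests = input_digests,
    n_loads = length(unique(loads$load_id)),
    n_bee_species = length(profiles),
    config = unclass(cfg), tiers = as.list(tiers),
    n_resamples = n_resamples, seed = seed,
    minor_threshold = minor_threshold)

  result <- structure(
    list(profiles = profiles, profiles_table = profiles_table(profiles),
         classification = classification, rarefaction = rarefaction,
         stats = stats_out, exclusions = exclusions, manifest = manifest),
    class = "pollen_pipeline")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(result$profiles_table,
                     file.path(out_dir, "profiles.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(classification),
                     file.path(out_dir, "classification.csv"),
                     row.names = FALSE)
    rar <- do.call(rbind, lapply(names(rarefaction), function(k) {
      cbind(tier = k, rarefaction[[k]])
    }))
    utils::write.csv(rar, file.path(out_dir, "rarefaction.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(stats = stats_out, exclusions = exclusions),
      file.path(out_dir, "stats.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "rows")
    manifest$outputs <- c("profiles.csv", "classification.csv",
                          "rarefaction.csv", "stats.json")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}

#' Human-readable summary of a pipeline run
#'
#' Renders a per-species table mirroring the shape of published host-range
#' tables — sample size, family composition (one decimal), pure-load and
#' presence percentages of the preferred host, category — followed by the
#' statistical summaries.
#'
#' @param result a `pollen_pipeline` from [run_pipeline()].
#' @return The per-species summary data.frame, invisibly; prints the report.
#' @export
pipeline_report <- function(result) {
  stopifnot(inherits(result, "pollen_pipeline"))
  cls <- result$classification
  if (nrow(cls) == 0) {
    cat("No bee species met the minimum sample size.\n")
    return(invisible(cls))
  }
  comp <- vapply(cls$bee_species, function(b) {
    fam <- sort(result$profiles[[b]]$family_level, decreasing = TRUE)
    paste0(names(fam), " ", formatC(fam, format = "f", digits = 1),
           collapse = ", ")
  }, character(1))
  tab <- data.frame(
    bee_species = cls$bee_species, n_loads = cls$n_loads,
    composition = unname(comp),
    pure_pct = round(cls$pure_pct, 1),
    presence_pct = round(cls$presence_pct, 1),
    category = cls$category, preferred_host = cls$preferred_host,
    stringsAsFactors = FALSE)
  cat("Diet characterisation (", nrow(tab), "bee species )\n")
  print(tab, right = FALSE, row.names = FALSE)
  if (length(result$exclusions$classification) > 0) {
    cat("Excluded (insufficient sample):",
        paste(result$exclusions$classification, collapse = ", "), "\n")
  }
  if (!is.null(result$stats$linear_model)) {
    lmout <- result$stats$linear_model
    slope <- lmout$coefficients[
      lmout$coefficients$term == "rarefied_breadth", ]
    cat(sprintf(
      "Breadth-occurrence linear model (%s): slope t = %.3f, p = %.4f, adjusted R^2 = %.3f (n = %d)\n",
      lmout$tier, slope$t, slope$p, lmout$adj_r_squared, lmout$n))
  }
  if (!is.null(result$stats$spearman)) {
    sp <- result$stats$spearman
    cat(sprintf(
      "Breadth-occurrence Spearman (%s): rho = %.3f, p = %.4f (n = %d)\n",
      sp$tier, sp$rho, sp$p_value, sp$n))
  }
  invisible(tab)
}
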