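#' Host-range categories
#'
#' The five host-range (lecty) categories, ordered from least to most
#' specialised: polylectic sensu stricto, polylectic with a strong
#' preference, mesolectic, broadly oligolectic (one plant family), narrowly
#' oligolectic (one plant genus).
#'
#' @format Character vector of the five category codes, least specialised
#'   first.
#' @export
lecty_categories <- c("polylectic_ss", "polylectic_strong_preference",
                      "mesolectic", "broadly_oligolectic",
                      "narrowly_oligolectic")

#' Specialisation rank of a host-range category
#'
#' @param category character vector of category codes.
#' @return Integer rank, 1 (polylectic s.s.) to 5 (narrowly oligolectic).
#' @export
lecty_rank <- function(category) {
  r <- match(category, lecty_categories)
  if (anyNA(r)) {
    stop("unknown category code(s): ",
         paste(unique(category[is.na(r)]), collapse = ", "))
  }
  r
}

#' Classification thresholds
#'
#' Configuration of the host-range decision rules. A bee species is
#' oligolectic on a genus or family when 95% of its pollen volume comes from
#' that group (`volume_threshold`) *and* 90% of its loads are pure loads of
#' it (`pure_threshold`); when the two criteria disagree, the category with
#' the lower degree of specialisation is used, so the species falls through
#' to the polylectic branches. A non-oligolect whose top family holds at
#' least `strong_pref_threshold` percent of the volume is polylectic with a
#' strong preference; one drawing on at most `mesolectic_family_count`
#' families (each >= `minor_family_threshold` percent) is mesolectic;
#' anything else is polylectic s.s. Classification requires at least
#' `min_loads` analysed loads.
#'
#' @param volume_threshold percent of total pollen volume from one group
#'   required by the volume criterion (default 95).
#' @param pure_threshold percent of loads that must be pure loads of one
#'   group under the pure-load criterion (default 90).
#' @param strong_pref_threshold top-family share defining a strong
#'   preference (default 70).
#' @param mesolectic_family_count maximum number of families for mesolecty
#'   (default 2).
#' @param minor_family_threshold percent share below which a family is not
#'   counted (default 1).
#' @param min_loads minimum sample size for classification (default 3).
#' @return A `lecty_config` list.
#' @export
lecty_config <- function(volume_threshold = 95, pure_threshold = 90,
                         strong_pref_threshold = 70,
                         mesolectic_family_count = 2L,
                         minor_family_threshold = 1,
                         min_loads = 3L) {
  stopifnot(volume_threshold > 0, volume_threshold <= 100,
            pure_threshold > 0, pure_threshold <= 100,
            strong_pref_threshold > 0, strong_pref_threshold <= 100,
            mesolectic_family_count >= 1, min_loads >= 1)
  structure(list(volume_threshold = volume_threshold,
                 pure_threshold = pure_threshold,
                 strong_pref_threshold = strong_pref_threshold,
                 mesolectic_family_count = as.integer(mesolectic_family_count),
                 minor_family_threshold = minor_family_threshold,
                 min_loads = as.integer(min_loads)),
            class = "lecty_config")
}

level_shares <- function(profile, level) {
  switch(level, genus = profile$genus_level, family = profile$family_level,
         stop("level must be 'genus' or 'family'"))
}

#' Oligolecty criteria
#'
#' `criterion_volume()` tests whether one genus or family accounts for at
#' least `volume_threshold` percent of the species' total pollen volume.
#' `criterion_pure_loads()` tests whether at least `pure_threshold` percent
#' of the species' loads are pure loads of one genus or family. Each returns
#' a verdict with the supporting value (the maximum share / pure-load
#' percentage at that level); the verdict fails when the profile carries no
#' information at that level.
#'
#' @param profile a `diet_profile`.
#' @param level `"genus"` or `"family"`.
#' @param cfg a `lecty_config`.
#' @return List with `criterion`, `level`, `passes`, `value`.
#' @export
criterion_volume <- function(profile, level = c("family", "genus"),
                             cfg = lecty_config()) {
  level <- match.arg(level)
  shares <- level_shares(profile, level)
  value <- if (length(shares) > 0) max(shares) else NA_real_
  list(criterion = "volume_95", level = level,
       passes = isTRUE(value >= cfg$volume_threshold), value = value)
}

#' @rdname criterion_volume
#' @export
criterion_pure_loads <- function(profile, level = c("family", "genus"),
                                 cfg = lecty_config()) {
  level <- match.arg(level)
  pure <- profile$pure_load_pct[[level]]
  value <- if (length(pure) > 0) max(pure) else NA_real_
  list(criterion = "pure_loads_90", level = level,
       passes = isTRUE(value >= cfg$pure_threshold), value = value)
}

#' Classify a bee species' host range
#'
#' Applies the decision tree over the dual oligolecty criteria:
#' \enumerate{
#'   \item both criteria pass at genus level: narrowly oligolectic;
#'   \item both pass at family level: broadly oligolectic;
#'   \item top family share >= `strong_pref_threshold`: polylectic with a
#'     strong preference;
#'   \item at most `mesolectic_family_count` families in the diet:
#'     mesolectic;
#'   \item otherwise polylectic s.s.
#' }
#' When exactly one oligolecty criterion passes, the species falls through
#' to steps 3--5: of the two answers, the category with the lower degree of
#' specialisation is used. Species with fewer than `min_loads` loads are
#' refused with an `insufficient_sample` error.
#'
#' @param profile a `diet_profile`.
#' @param cfg a `lecty_config`.
#' @return A `lecty_result` list: `bee_species`, `category`, `rank`,
#'   `preferred_host`, `top_family_share`, `n_families`, `n_loads`, and the
#'   four criterion `verdicts`.
#' @export
classify <- function(profile, cfg = lecty_config()) {
  if (profile$n_loads < cfg$min_loads) {
    stop(structure(
      class = c("insufficient_sample", "error", "condition"),
      list(message = paste0("insufficient sample: ", profile$bee_species,
                            " has ", profile$n_loads, " loads (minimum ",
                            cfg$min_loads, ")"),
           call = sys.call(-1))))
  }
  verdicts <- list(
    volume_genus = criterion_volume(profile, "genus", cfg),
    pure_genus = criterion_pure_loads(profile, "genus", cfg),
    volume_family = criterion_volume(profile, "family", cfg),
    pure_family = criterion_pure_loads(profile, "family", cfg)
  )
  fam <- profile$family_level
  top_family <- names(fam)[which.max(fam)]
  top_share <- max(fam)
  n_fam <- count_families(profile, cfg$minor_family_threshold)

  if (verdicts$volume_genus$passes && verdicts$pure_genus$passes) {
    g <- profile$genus_level
    category <- "narrowly_oligolectic"
    preferred <- names(g)[which.max(g)]
  } else if (verdicts$volume_family$passes && verdicts$pure_family$passes) {
    category <- "broadly_oligolectic"
    preferred <- top_family
  } else if (top_share >= cfg$strong_pref_threshold) {
    category <- "polylectic_strong_preference"
    preferred <- top_family
  } else if (n_fam <= cfg$mesolectic_family_count) {
    category <- "mesolectic"
    preferred <- top_family
  } else {
    category <- "polylectic_ss"
    preferred <- top_family
  }
  structure(list(bee_species = profile$bee_species, category = category,
                 rank = lecty_rank(category), preferred_host = preferred,
                 top_family_share = top_share, n_families = n_fam,
                 n_loads = profile$n_loads, verdicts = verdicts),
            class = "lecty_result")
}

#' @export
print.lecty_result <- function(x, ...) {
  cat(x$bee_species, "->", x$category, "(preferred host:", x$preferred_host,
      "; top family share", formatC(x$top_family_share, format = "f",
                                    digits = 1), "% over", x$n_loads,
      "loads)\n")
  invisible(x)
}

#' Classify a collection of profiles, with optional concordance report
#'
#' Runs [classify()] over every profile with at least `min_loads` loads and
#' tabulates the results; when reference categories are supplied (e.g. the
#' published categories of a reference table) a per-species match column and
#' a concordance summary are attached.
#'
#' @param profiles list of `diet_profile` objects.
#' @param cfg a `lecty_config`.
#' @param reference optional named character vector of category codes
#'   (names = bee species) to compare against.
#' @return data.frame with one row per classified species (columns
#'   `bee_species`, `category`, `preferred_host`, `top_family_share_pct`,
#'   `pure_pct`, `presence_pct`, `n_loads`, `volume_pass`, `pure_pass`,
#'   plus `reference_category` / `match` when `reference` is given).
#'   Attributes: `excluded` (species refused for sample size) and, with a
#'   reference, `concordance` (matches / total).
#' @export
classify_table <- function(profiles, cfg = lecty_config(), reference = NULL) {
  excluded <- character(0)
  rows <- list()
  for (p in profiles) {
    if (p$n_loads < cfg$min_loads) {
      excluded <- c(excluded, p$bee_species)
      next
    }
    r <- classify(p, cfg)
    pure_val <- r$verdicts$pure_family$value
    pres_map <- p$presence_pct[["family"]]
    pres_val <- if (length(pres_map) > 0) max(pres_map) else NA_real_
    rows[[length(rows) + 1]] <- data.frame(
      bee_species = r$bee_species, category = r$category,
      preferred_host = r$preferred_host,
      top_family_share_pct = r$top_family_share,
      pure_pct = pure_val, presence_pct = pres_val,
      n_loads = r$n_loads,
      volume_pass = r$verdicts$volume_family$passes,
      pure_pass = r$verdicts$pure_family$passes,
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(bee_species = character(0), category = character(0),
               preferred_host = character(0),
               top_family_share_pct = numeric(0), pure_pct = numeric(0),
               presence_pct = numeric(0), n_loads = integer(0),
               volume_pass = logical(0), pure_pass = logical(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  if (!is.null(reference)) {
    out$reference_category <- unname(reference[out$bee_species])
    out$match <- !is.na(out$reference_category) &
      out$category == out$reference_category
    attr(out, "concordance") <- c(matches = sum(out$match),
                                  total = nrow(out))
  }
  out
}
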