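#' Plant taxonomy tables
#'
#' A taxonomy table maps pollen taxon labels to genus and family. Pollen can
#' often be identified only to genus (e.g. *Brassica*, *Plantago*,
#' *Geranium*), so each label carries a `resolution` flag saying whether it
#' denotes a plant species, a genus, or a family.
#'
#' @param df data.frame with columns `taxon_label`, `genus`, `family`,
#'   `resolution` (one of `"species"`, `"genus"`, `"family"`).
#' @return A validated `pollen_taxonomy` data.frame.
#' @examples
#' tax <- pollen_taxonomy(data.frame(
#'   taxon_label = c("Centaurea nigra", "Brassica"),
#'   genus = c("Centaurea", "Brassica"),
#'   family = c("Asteraceae", "Brassicaceae"),
#'   resolution = c("species", "genus")
#' ))
#' @export
pollen_taxonomy <- function(df) {
  required <- c("taxon_label", "genus", "family", "resolution")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("taxonomy is missing column(s): ", paste(missing, collapse = ", "))
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in required) df[[col]] <- trimws(as.character(df[[col]]))

  bad_res <- !df$resolution %in% c("species", "genus", "family")
  if (any(bad_res)) {
    stop("invalid resolution value(s): ",
         paste(unique(df$resolution[bad_res]), collapse = ", "))
  }
  if (any(is.na(df$family) | df$family == "")) {
    stop("taxonomy rows with empty family: row(s) ",
         paste(which(is.na(df$family) | df$family == ""), collapse = ", "))
  }
  sp <- df$resolution == "species"
  if (any(sp & (df$genus == "" | df$taxon_label == ""))) {
    stop("species-resolution rows must carry genus and label")
  }
  key <- taxon_key(df$taxon_label)
  if (anyDuplicated(key)) {
    dups <- unique(df$taxon_label[duplicated(key)])
    stop("duplicate taxon label(s) in taxonomy: ", paste(dups, collapse = ", "))
  }
  class(df) <- c("pollen_taxonomy", "data.frame")
  df
}

#' Read a plant taxonomy table from CSV
#'
#' Expected header: `taxon_label,genus,family,resolution`.
#'
#' @param path path to a CSV file.
#' @return A `pollen_taxonomy` data.frame.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("taxonomy file not found: ", path)
  pollen_taxonomy(utils::read.csv(path, stringsAsFactors = FALSE))
}

# canonical matching key: trimmed, case-folded
taxon_key <- function(labels) tolower(trimws(as.character(labels)))

taxon_index <- function(taxonomy, labels) {
  idx <- match(taxon_key(labels), taxon_key(taxonomy$taxon_label))
  idx
}

#' Look up the family (or genus) of pollen taxon labels
#'
#' Labels are matched case-insensitively after whitespace trimming. For
#' `taxon_genus`, labels whose taxonomy row has no genus (family-resolution
#' pollen) fall back to the label itself, so each such pollen type still
#' counts as its own type at genus level.
#'
#' @param taxonomy a `pollen_taxonomy`.
#' @param labels character vector of taxon labels.
#' @return Character vector, same length as `labels`.
#' @export
taxon_family <- function(taxonomy, labels) {
  idx <- taxon_index(taxonomy, labels)
  if (anyNA(idx)) {
    stop("unknown taxon label(s): ",
         paste(unique(labels[is.na(idx)]), collapse = ", "))
  }
  taxonomy$family[idx]
}

#' @rdname taxon_family
#' @export
taxon_genus <- function(taxonomy, labels) {
  idx <- taxon_index(taxonomy, labels)
  if (anyNA(idx)) {
    stop("unknown taxon label(s): ",
         paste(unique(labels[is.na(idx)]), collapse = ", "))
  }
  g <- taxonomy$genus[idx]
  blank <- is.na(g) | g == ""
  g[blank] <- taxonomy$taxon_label[idx][blank]
  g
}
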