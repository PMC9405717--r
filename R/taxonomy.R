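#' Construct and validate a taxonomy table
#'
#' The rank lineage every assignment decision consults. Each row is a species
#' with its genus, optional tribe, family and clade. The table must satisfy:
#' species names unique; each genus in exactly one family; each family in
#' exactly one clade; a tribe, where present, nested in exactly one family.
#'
#' @param df data.frame with columns `species_name`, `genus`, `tribe`
#'   (may be `NA`), `family`, `clade`.
#' @return a validated `data.frame` of class `taxonomy_table`.
#' @export
taxonomy_table <- function(df) {
  req <- c("species_name", "genus", "tribe", "family", "clade")
  if (!all(req %in% names(df)))
    stop_hf("taxonomy table needs columns: ", paste(req, collapse = ", "))
  df <- as.data.frame(df)[req]
  df$species_name <- normalize_binomial(df$species_name)
  df$tribe[!is.na(df$tribe) & !nzchar(df$tribe)] <- NA_character_
  if (anyDuplicated(df$species_name))
    stop_hf("duplicate species_name in taxonomy: ",
            paste(unique(df$species_name[duplicated(df$species_name)]), collapse = ", "))
  chk <- function(child, parent, lab) {
    tab <- unique(df[!is.na(df[[child]]), c(child, parent)])
    bad <- tab[[child]][duplicated(tab[[child]])]
    if (length(bad))
      stop_hf(lab, " maps to multiple parents: ", paste(unique(bad), collapse = ", "))
  }
  chk("genus", "family", "genus")
  chk("family", "clade", "family")
  chk("tribe", "family", "tribe")
  class(df) <- c("taxonomy_table", "data.frame")
  df
}

#' Read / write a taxonomy table as TSV
#'
#' @param path file path (UTF-8, tab-delimited, header row).
#' @return `read_taxonomy_tsv` returns a `taxonomy_table`.
#' @export
read_taxonomy_tsv <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE,
                          na.strings = c("", "NA"), data.table = FALSE)
  taxonomy_table(df)
}

#' @rdname read_taxonomy_tsv
#' @param taxonomy a `taxonomy_table`.
#' @export
write_taxonomy_tsv <- function(taxonomy, path) {
  data.table::fwrite(as.data.frame(taxonomy), path, sep = "\t", na = "NA",
                     quote = FALSE)
  invisible(path)
}

#' Resolve taxon labels to lineages
#'
#' Maps labels at a given rank onto lineage rows (genus, tribe, family,
#' clade). Species labels resolve through their taxonomy row; genus labels
#' through the (unique) lineage of that genus; tribe/family labels through
#' the tribe/family columns.
#'
#' @param taxonomy a `taxonomy_table`.
#' @param labels character vector of taxon names.
#' @param ranks character vector (recycled) in
#'   `c("species","genus","tribe","family")`.
#' @return data.frame with columns label, rank, genus, tribe, family, clade
#'   (`NA` where a level is undefined for the rank).
#' @export
resolve_labels <- function(taxonomy, labels, ranks) {
  ranks <- rep_len(ranks, length(labels))
  gen <- unique(as.data.frame(taxonomy)[c("genus", "family", "clade")])
  gtribe <- unique(as.data.frame(taxonomy)[c("genus", "tribe")])
  # genus -> tribe only when unambiguous across its species
  amb <- gtribe$genus[duplicated(gtribe$genus)]
  gtribe <- gtribe[!gtribe$genus %in% amb, , drop = FALSE]
  out <- data.frame(label = labels, rank = ranks, genus = NA_character_,
                    tribe = NA_character_, family = NA_character_,
                    clade = NA_character_, stringsAsFactors = FALSE)
  fam2clade <- unique(as.data.frame(taxonomy)[c("family", "clade")])
  tribe2fam <- unique(as.data.frame(taxonomy)[!is.na(taxonomy$tribe),
                                              c("tribe", "family")])
  for (i in seq_along(labels)) {
    lab <- labels[i]
    switch(ranks[i],
      species = {
        j <- match(normalize_binomial(lab), taxonomy$species_name)
        if (is.na(j)) stop_hf("unresolvable species label: ", lab)
        out$genus[i] <- taxonomy$genus[j]
        out$tribe[i] <- taxonomy$tribe[j]
        out$family[i] <- taxonomy$family[j]
        out$clade[i] <- taxonomy$clade[j]
      },
      genus = {
        j <- match(lab, gen$genus)
        if (is.na(j)) stop_hf("unresolvable genus label: ", lab)
        out$genus[i] <- lab
        k <- match(lab, gtribe$genus)
        out$tribe[i] <- if (is.na(k)) NA_character_ else gtribe$tribe[k]
        out$family[i] <- gen$family[j]
        out$clade[i] <- gen$clade[j]
      },
      tribe = {
        j <- match(lab, tribe2fam$tribe)
        if (is.na(j)) stop_hf("unresolvable tribe label: ", lab)
        out$tribe[i] <- lab
        out$family[i] <- tribe2fam$family[j]
        out$clade[i] <- fam2clade$clade[match(out$family[i], fam2clade$family)]
      },
      family = {
        j <- match(lab, fam2clade$family)
        if (is.na(j)) stop_hf("unresolvable family label: ", lab)
        out$family[i] <- lab
        out$clade[i] <- fam2clade$clade[j]
      },
      stop_hf("unknown rank: ", ranks[i])
    )
  }
  out
}

#' Read a species list
#'
#' A species list is a non-empty character set of binomials, normalized and
#' checked against the taxonomy. Unresolvable names are reported in the
#' `"unresolved"` attribute, never silently dropped.
#'
#' @param x character vector of species binomials, or a path to a one-column
#'   (or headered `species_name`) TSV when `from_file = TRUE`.
#' @param taxonomy a `taxonomy_table` used to resolve names.
#' @param from_file read `x` as a TSV path.
#' @return character vector of resolved species names with attribute
#'   `unresolved` (character vector of names absent from the taxonomy).
#' @export
species_list <- function(x, taxonomy, from_file = FALSE) {
  if (from_file) {
    df <- data.table::fread(x, sep = "\t", header = TRUE, data.table = FALSE)
    col <- if ("species_name" %in% names(df)) "species_name" else names(df)[1]
    x <- df[[col]]
  }
  x <- unique(normalize_binomial(x))
  x <- x[nzchar(x)]
  if (!length(x)) stop_hf("species list is empty")
  ok <- x %in% taxonomy$species_name
  out <- x[ok]
  attr(out, "unresolved") <- x[!ok]
  out
}
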