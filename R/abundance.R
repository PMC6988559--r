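#' Construct a validated abundance table
#'
#' An abundance table is the community matrix every downstream step
#' consumes: one row per (site, period) survey, one column per species,
#' cells holding the number of individuals collected. It is stored as an
#' integer matrix with `site_id` and `period` attributes aligned to rows.
#'
#' @param counts numeric matrix of non-negative integer counts, one row per
#'   survey, one column per species (column names = species names).
#' @param site_id character vector of site identifiers, one per row.
#' @param period character vector of period labels (e.g. "T1", "T2"), one
#'   per row.
#' @return an object of class `abundance_table`.
#' @export
abundance_table <- function(counts, site_id, period) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  site_id <- as.character(site_id)
  period <- as.character(period)
  if (nrow(counts) != length(site_id) || nrow(counts) != length(period))
    stop("site_id and period must each have one entry per row of counts")
  if (is.null(colnames(counts)))
    stop("counts must have species column names")
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "invalid count at site '%s', period '%s', species '%s': %s",
      site_id[bad[1, 1]], period[bad[1, 1]],
      colnames(counts)[bad[1, 2]], counts[bad[1, 1], bad[1, 2]]))
  }
  if (anyDuplicated(colnames(counts)))
    stop("duplicate species names: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  key <- paste(site_id, period, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicate (site_id, period) row key: ",
         gsub("\r", " / ", d, fixed = TRUE))
  }
  if (nrow(counts) > 0 && any(rowSums(counts) == 0)) {
    i <- which(rowSums(counts) == 0)[1]
    stop(sprintf("row (%s, %s) has no individuals; empty surveys are not retained",
                 site_id[i], period[i]))
  }
  rownames(counts) <- paste(site_id, period, sep = "|")
  structure(counts,
            site_id = site_id, period = period,
            class = c("abundance_table", "matrix", "array"))
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table> %d surveys x %d species; periods: %s\n",
              nrow(x), ncol(x),
              paste(unique(attr(x, "period")), collapse = ", ")))
  invisible(x)
}

#' Row site identifiers of an abundance table
#' @param table an `abundance_table`.
#' @return character vector, one entry per row.
#' @export
ab_sites <- function(table) attr(table, "site_id")

#' Row period labels of an abundance table
#' @param table an `abundance_table`.
#' @return character vector, one entry per row.
#' @export
ab_periods <- function(table) attr(table, "period")

#' Restrict an abundance table to one period
#'
#' All species columns are retained, including those absent (all-zero)
#' within the period: the dissimilarity and diversity indices are
#' insensitive to all-zero columns and retention simplifies persistence
#' bookkeeping.
#'
#' @param table an `abundance_table`.
#' @param period period label to keep.
#' @return an `abundance_table` with rows of that period only.
#' @export
subset_period <- function(table, period) {
  keep <- ab_periods(table) == period
  if (!any(keep)) stop("period '", period, "' not present in table")
  abundance_table(unclass(table)[keep, , drop = FALSE],
                  ab_sites(table)[keep], ab_periods(table)[keep])
}

#' Read an abundance table from CSV/TSV
#'
#' Two dialects are accepted. `long` (canonical on disk) has the columns
#' `site_id, period, species, count`, one record per positive cell;
#' duplicate (site, period, species) triples are an error, never summed.
#' `wide` has one row per (site_id, period) and one column per species;
#' empty cells become zero counts.
#'
#' @param path file path; field separator is inferred from the extension
#'   (`.tsv` = tab, otherwise comma).
#' @param dialect `"long"` or `"wide"`.
#' @return an `abundance_table`.
#' @export
read_abundance_table <- function(path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = NA)
  if (dialect == "long") {
    need <- c("site_id", "period", "species", "count")
    if (!all(need %in% names(df)))
      stop("long dialect requires columns: ", paste(need, collapse = ", "))
    cnt <- suppressWarnings(as.numeric(df$count))
    bad <- which(is.na(cnt) | cnt < 0 | cnt != round(cnt))
    if (length(bad) > 0)
      stop(sprintf("invalid count '%s' at record %d (site %s, period %s, species %s)",
                   df$count[bad[1]], bad[1], df$site_id[bad[1]],
                   df$period[bad[1]], df$species[bad[1]]))
    trip <- paste(df$site_id, df$period, df$species, sep = "\r")
    if (anyDuplicated(trip)) {
      d <- strsplit(trip[duplicated(trip)][1], "\r", fixed = TRUE)[[1]]
      stop(sprintf("duplicate record for site %s, period %s, species %s",
                   d[1], d[2], d[3]))
    }
    rows <- unique(data.frame(site_id = df$site_id, period = df$period,
                              stringsAsFactors = FALSE))
    key <- paste(rows$site_id, rows$period, sep = "\r")
    sp <- sort(unique(df$species))
    m <- matrix(0, nrow(rows), length(sp), dimnames = list(NULL, sp))
    i <- match(paste(df$site_id, df$period, sep = "\r"), key)
    j <- match(df$species, sp)
    m[cbind(i, j)] <- cnt
    abundance_table(m, rows$site_id, rows$period)
  } else {
    need <- c("site_id", "period")
    if (!all(need %in% names(df)))
      stop("wide dialect requires columns site_id and period")
    spcols <- setdiff(names(df), need)
    m <- as.matrix(df[, spcols, drop = FALSE])
    storage.mode(m) <- "double"
    m[is.na(m)] <- 0
    abundance_table(m, df$site_id, df$period)
  }
}

#' Write an abundance table to CSV/TSV
#'
#' @param table an `abundance_table`.
#' @param path output path; `.tsv` extension selects tab separation.
#' @param dialect `"long"` (only positive cells, canonical) or `"wide"`.
#' @export
write_abundance_table <- function(table, path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  if (dialect == "long") {
    idx <- which(unclass(table) > 0, arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    df <- data.frame(site_id = ab_sites(table)[idx[, 1]],
                     period = ab_periods(table)[idx[, 1]],
                     species = colnames(table)[idx[, 2]],
                     count = unclass(table)[idx],
                     stringsAsFactors = FALSE)
  } else {
    df <- data.frame(site_id = ab_sites(table), period = ab_periods(table),
                     stringsAsFactors = FALSE, check.names = FALSE)
    df <- cbind(df, as.data.frame(unclass(table), check.names = FALSE))
    rownames(df) <- NULL
  }
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Default taxon harmonization map
#'
#' The three survey-era reconciliations applied before any analysis of the
#' fish resurvey data: two congeneric collapses for species not
#' distinguished in the earlier survey (*Campostoma*, *Fundulus*) and one
#' taxonomic reassignment (*Notropis rubellus* to *N. suttkusi*).
#'
#' @return data.frame with columns `source`, `target`, `kind`.
#' @export
default_taxon_map <- function() {
  data.frame(
    source = c("Campostoma anomalum", "Campostoma spadiceum",
               "Fundulus notatus", "Fundulus olivaceus",
               "Notropis rubellus"),
    target = c("Campostoma spp.", "Campostoma spp.",
               "Fundulus spp.", "Fundulus spp.",
               "Notropis suttkusi"),
    kind = c("merge", "merge", "merge", "merge", "rename"),
    stringsAsFactors = FALSE
  )
}

#' Read a taxon merge map from CSV
#'
#' @param path two-column CSV (`source`, `target`) with an optional `kind`
#'   column (`merge` or `rename`; default `merge`).
#' @return data.frame usable by [harmonize_taxa()].
#' @export
read_taxon_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("source", "target") %in% names(df)))
    stop("taxon map requires columns source and target")
  if (is.null(df$kind)) df$kind <- "merge"
  validate_taxon_map(df)
}

validate_taxon_map <- function(map) {
  stopifnot(all(c("source", "target", "kind") %in% names(map)))
  if (!all(map$kind %in% c("merge", "rename")))
    stop("taxon map kind must be 'merge' or 'rename'")
  chained <- intersect(map$source, map$target)
  if (length(chained) > 0)
    stop("chained taxon mapping (target also appears as source): ",
         paste(chained, collapse = ", "))
  map
}

#' Harmonize taxon names in an abundance table
#'
#' Applies merge entries (source columns summed into the target column)
#' and rename entries (column relabelled). Row totals are conserved
#' exactly. A rename whose target already exists in the table is carried
#' out as an implicit merge, with a message. Map sources absent from the
#' table are skipped silently.
#'
#' @param table an `abundance_table`.
#' @param map data.frame with columns `source`, `target`, `kind`; defaults
#'   to [default_taxon_map()].
#' @return harmonized `abundance_table`.
#' @export
harmonize_taxa <- function(table, map = default_taxon_map()) {
  map <- validate_taxon_map(map)
  m <- unclass(table)
  for (i in seq_len(nrow(map))) {
    src <- map$source[i]; tgt <- map$target[i]; kind <- map$kind[i]
    if (!(src %in% colnames(m))) next
    if (tgt %in% colnames(m)) {
      if (kind == "rename")
        message("rename ", src, " -> ", tgt,
                ": target already present, counts merged")
      m[, tgt] <- m[, tgt] + m[, src]
      m <- m[, colnames(m) != src, drop = FALSE]
    } else {
      colnames(m)[colnames(m) == src] <- tgt
    }
  }
  abundance_table(m, ab_sites(table), ab_periods(table))
}

#' Pool sites of an abundance table into clusters
#'
#' Produces the cluster-by-species matrix used at every spatial grain:
#' for each (cluster, period), cell values are the sums of the member
#' sites' counts. Count totals per period are conserved exactly.
#'
#' @param table an `abundance_table`.
#' @param groups named vector or list mapping every `site_id` in the table
#'   to a cluster identifier.
#' @return an `abundance_table` whose "sites" are cluster identifiers.
#' @export
pool_sites <- function(table, groups) {
  groups <- unlist(groups)
  sites <- ab_sites(table)
  orphan <- setdiff(unique(sites), names(groups))
  if (length(orphan) > 0)
    stop("sites missing from grouping: ", paste(orphan, collapse = ", "))
  cl <- as.character(groups[sites])
  per <- ab_periods(table)
  key <- paste(cl, per, sep = "\r")
  ukey <- unique(key)
  m <- rowsum(unclass(table), group = factor(key, levels = ukey))
  parts <- do.call(rbind, strsplit(ukey, "\r", fixed = TRUE))
  abundance_table(m, parts[, 1], parts[, 2])
}

#' Convert counts to presence/absence
#'
#' @param table an `abundance_table`.
#' @return an `abundance_table` of 0/1 indicators (idempotent).
#' @export
to_presence_absence <- function(table) {
  m <- unclass(table)
  abundance_table((m > 0) * 1, ab_sites(table), ab_periods(table))
}
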