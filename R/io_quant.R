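#' Read a spectrum-level (PSM) quantification table
#'
#' Parses a TSV/CSV table of quantified spectra. Each row is one PSM with
#' its reporter intensities across the TMT channels plus the two precursor
#' quality measures the filters act on: signal-to-interference (s2i) of the
#' isolation window and precursor-to-threshold ratio (p2t), a
#' signal-to-noise proxy.
#'
#' @param path path to a TSV or CSV file (delimiter inferred from the
#'   extension, tab unless the file ends in `.csv`) with columns
#'   `spectrum_id`, `protein_id`, `condition`, `replicate`, `s2i`, `p2t`,
#'   and one column per channel label of `channel_map`.
#' @param channel_map a [channel_map] naming the reporter channels.
#' @return A data.frame with one row per PSM, columns as above; reporter
#'   columns are numeric with `NA` for missing or unparseable cells.
#' @export
read_psm_table <- function(path, channel_map = default_channel_map()) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  needed <- c("spectrum_id", "protein_id", "condition", "replicate",
              "s2i", "p2t", channel_map$channel_labels)
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    stop("PSM table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(raw) == 0) {
    out <- raw[, needed, drop = FALSE]
    num_cols <- c("replicate", "s2i", "p2t", channel_map$channel_labels)
    for (cl in num_cols) out[[cl]] <- numeric(0)
    return(out)
  }
  if (anyDuplicated(raw$spectrum_id)) {
    stop("duplicate spectrum_id in PSM table: ",
         paste(unique(raw$spectrum_id[duplicated(raw$spectrum_id)])[1:3],
               collapse = ", "))
  }
  out <- raw[, needed, drop = FALSE]
  num <- function(x) suppressWarnings(as.numeric(x))
  out$replicate <- num(out$replicate)
  out$s2i <- num(out$s2i)
  out$p2t <- num(out$p2t)
  for (cl in channel_map$channel_labels) out[[cl]] <- num(out[[cl]])
  bad_s2i <- !is.na(out$s2i) & (out$s2i < 0 | out$s2i > 1)
  if (any(bad_s2i)) stop("s2i outside [0,1] for spectrum ",
                         out$spectrum_id[which(bad_s2i)[1]])
  bad_p2t <- !is.na(out$p2t) & out$p2t < 0
  if (any(bad_p2t)) stop("negative p2t for spectrum ",
                         out$spectrum_id[which(bad_p2t)[1]])
  neg <- vapply(channel_map$channel_labels,
                function(cl) any(out[[cl]] < 0, na.rm = TRUE), logical(1))
  if (any(neg)) stop("negative reporter intensity in channel(s): ",
                     paste(channel_map$channel_labels[neg], collapse = ", "))
  rownames(out) <- NULL
  out
}

#' Filter PSMs on precursor quality
#'
#' Discards spectra with signal-to-interference strictly below `s2i_min`
#' (coisolation interference) or precursor-to-threshold ratio strictly
#' below `p2t_min` (low signal-to-noise). Records sitting exactly at a
#' threshold are retained. PSMs with a missing quality value are discarded.
#'
#' @param psms data.frame as returned by [read_psm_table()].
#' @param s2i_min minimum signal-to-interference, in `[0,1]`; default 0.5.
#' @param p2t_min minimum precursor-to-threshold ratio; default 4.
#' @return The retained rows, original order preserved. The attribute
#'   `"filter_counts"` carries `c(input=, retained=, discarded=)`.
#' @examples
#' psms <- data.frame(spectrum_id = letters[1:3], protein_id = "P1",
#'                    condition = "mock", replicate = 1,
#'                    s2i = c(0.6, 0.4, 0.5), p2t = c(10, 10, 4))
#' filter_psms(psms)  # keeps rows 1 and 3
#' @export
filter_psms <- function(psms, s2i_min = 0.5, p2t_min = 4) {
  stopifnot(is.finite(s2i_min), is.finite(p2t_min),
            s2i_min >= 0, s2i_min <= 1)
  if (nrow(psms) == 0) {
    attr(psms, "filter_counts") <- c(input = 0, retained = 0, discarded = 0)
    return(psms)
  }
  keep <- !is.na(psms$s2i) & !is.na(psms$p2t) &
    psms$s2i >= s2i_min & psms$p2t >= p2t_min
  out <- psms[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_counts") <- c(input = nrow(psms),
                                  retained = sum(keep),
                                  discarded = sum(!keep))
  out
}

#' Roll PSM reporter intensities up to protein level
#'
#' Sums reporter intensities over all PSMs of a protein within each
#' (condition, replicate, channel) cell — the standard roll-up for TMT
#' reporter quantification — and attaches temperatures via the channel
#' map, yielding the long protein quantification table the rest of the
#' pipeline operates on.
#'
#' @param psms filtered PSM data.frame.
#' @param channel_map a [channel_map].
#' @return A long data.frame with columns `protein_id`, `condition`,
#'   `replicate`, `temperature_c`, `intensity`. Cells with no contributing
#'   PSM are absent (implicitly missing); a cell where all contributing
#'   PSMs are `NA` has `intensity = NA`.
#' @export
aggregate_psms_to_protein <- function(psms, channel_map = default_channel_map()) {
  empty <- data.frame(protein_id = character(0), condition = character(0),
                      replicate = integer(0), temperature_c = numeric(0),
                      intensity = numeric(0))
  if (nrow(psms) == 0) return(empty)
  pieces <- vector("list", length(channel_map$channel_labels))
  for (k in seq_along(channel_map$channel_labels)) {
    cl <- channel_map$channel_labels[k]
    vals <- psms[[cl]]
    present <- !is.na(vals)
    if (!any(present)) next
    key <- interaction(psms$protein_id, psms$condition, psms$replicate,
                       drop = TRUE, sep = "\r")
    # sum over observed PSMs; groups with zero observed PSMs dropped
    sums <- tapply(vals[present], key[present], sum)
    parts <- do.call(rbind, strsplit(names(sums), "\r", fixed = TRUE))
    pieces[[k]] <- data.frame(protein_id = parts[, 1],
                              condition = parts[, 2],
                              replicate = as.integer(parts[, 3]),
                              temperature_c = channel_map$temperatures_c[k],
                              intensity = as.numeric(sums))
  }
  out <- do.call(rbind, pieces)
  if (is.null(out)) return(empty)
  out <- out[order(out$protein_id, out$condition, out$replicate,
                   out$temperature_c), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Require replicate support per condition
#'
#' Keeps a protein within a condition only if it was observed (at least one
#' non-missing intensity) in at least `min_replicates` biological
#' replicates of that condition; otherwise the protein's rows are dropped
#' from that condition (other conditions are unaffected).
#'
#' @param table long protein quantification data.frame
#'   (`protein_id`, `condition`, `replicate`, `temperature_c`, `intensity`).
#' @param min_replicates minimum replicates with support; default 2.
#' @return The filtered table, row order preserved.
#' @export
require_replicate_support <- function(table, min_replicates = 2) {
  stopifnot(min_replicates >= 1)
  if (nrow(table) == 0) return(table)
  obs <- table[!is.na(table$intensity), c("protein_id", "condition", "replicate")]
  obs <- unique(obs)
  key <- paste(obs$protein_id, obs$condition, sep = "\r")
  nrep <- tapply(obs$replicate, key, function(x) length(unique(x)))
  ok <- names(nrep)[nrep >= min_replicates]
  keep <- paste(table$protein_id, table$condition, sep = "\r") %in% ok
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a result table as TSV
#'
#' Writes tab-separated UTF-8 output with a header row, `NA` for missing
#' values and numeric columns formatted at 6 significant digits. Rows are
#' sorted on the sort columns that are present (by default protein then
#' comparison) for deterministic output.
#'
#' @param rows a data.frame.
#' @param path output file path.
#' @param sort_by columns to sort on when present.
#' @return Invisibly, the path.
#' @export
write_results_table <- function(rows, path,
                                sort_by = c("protein_id", "comparison")) {
  stopifnot(is.data.frame(rows))
  sb <- intersect(sort_by, names(rows))
  if (length(sb) > 0 && nrow(rows) > 1) {
    rows <- rows[do.call(order, rows[sb]), , drop = FALSE]
  }
  fmt <- rows
  for (cl in names(fmt)) {
    if (is.double(fmt[[cl]])) {
      v <- fmt[[cl]]
      s <- formatC(signif(v, 6), format = "g", digits = 6)
      s[is.na(v)] <- NA
      fmt[[cl]] <- s
    }
  }
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(fmt, con, sep = "\t", quote = FALSE, na = "NA",
                     row.names = FALSE)
  invisible(path)
}

#' Read a long protein quantification table
#'
#' @param path TSV with columns `protein_id`, `condition`, `replicate`,
#'   `temperature_c`, `intensity` (`NA` for missing).
#' @return data.frame in the pipeline's long layout.
#' @export
read_protein_quant <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, na.strings = "NA",
                           check.names = FALSE)
  needed <- c("protein_id", "condition", "replicate", "temperature_c",
              "intensity")
  missing_cols <- setdiff(needed, names(out))
  if (length(missing_cols) > 0) {
    stop("protein quant table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  key <- paste(out$protein_id, out$condition, out$replicate,
               out$temperature_c)
  if (anyDuplicated(key)) {
    stop("duplicate (protein, condition, replicate, temperature) rows")
  }
  out[needed]
}

#' Read a protein-complex membership table
#'
#' @param path TSV with columns `complex_id`, `complex_name`, `subunits`
#'   (semicolon-separated protein identifiers) — the column subset of a
#'   CORUM-style download.
#' @return data.frame with one row per complex and a list-column
#'   `subunits` of unique member identifiers.
#' @export
read_complex_table <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "\"",
                           check.names = FALSE)
  needed <- c("complex_id", "complex_name", "subunits")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    stop("complex table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  subunits <- lapply(strsplit(as.character(raw$subunits), ";", fixed = TRUE),
                     function(x) unique(trimws(x[nzchar(trimws(x))])))
  if (any(lengths(subunits) == 0)) stop("complex with empty subunit list")
  data.frame(complex_id = as.character(raw$complex_id),
             complex_name = as.character(raw$complex_name),
             subunits = I(subunits))
}
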