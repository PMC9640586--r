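# Readers and writers for the pipeline's file formats: FASTA alignments
# (via ape), sequence metadata TSV, occurrence and fruit CSVs, and ESRI
# ASCII grids. Readers validate and refuse malformed input rather than
# coercing silently.

#' Read an aligned FASTA file
#'
#' Accepts multi-line wrapped records and CRLF line endings; the sequence
#' id is the first whitespace-delimited token of the header; residues are
#' uppercased.
#'
#' @param path Path to a FASTA file.
#' @param validate_alignment If `TRUE` (default), require equal lengths and
#'   return an [aligned_sequences()] object.
#' @return An [aligned_sequences()] data.frame (or a bare data.frame with
#'   `seq_id`, `residues` when `validate_alignment = FALSE`).
#' @export
read_fasta <- function(path, validate_alignment = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop(path, ": empty FASTA file")
  dna <- ape::read.FASTA(path)
  if (!length(dna)) stop(path, ": no FASTA records")
  ids <- vapply(strsplit(names(dna), "\\s+"), `[`, character(1), 1)
  seqs <- toupper(vapply(as.character(dna), paste, character(1),
                         collapse = ""))
  if (!validate_alignment)
    return(data.frame(seq_id = ids, residues = unname(seqs),
                      stringsAsFactors = FALSE))
  aligned_sequences(ids, unname(seqs))
}

#' Write sequences to FASTA
#'
#' @param alignment An [aligned_sequences()] data.frame (or anything with
#'   `seq_id` and `residues` columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(alignment, path) {
  dna <- ape::as.DNAbin(strsplit(tolower(alignment$residues), "",
                                 fixed = TRUE))
  names(dna) <- alignment$seq_id
  ape::write.FASTA(dna, path)
  invisible(path)
}

#' Read a sequence metadata table
#'
#' Tab-separated `seq_id`, `locality`, `group` (header required) and attach
#' it to an alignment.
#'
#' @param path Path to the TSV file.
#' @param alignment Optional [aligned_sequences()] to annotate.
#' @return The metadata data.frame, or the annotated alignment when one is
#'   supplied.
#' @export
read_meta_tsv <- function(path, alignment = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  meta <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("seq_id", "locality", "group")
  miss <- setdiff(req, names(meta))
  if (length(miss))
    stop(path, ": missing metadata columns: ", paste(miss, collapse = ", "))
  if (is.null(alignment)) return(meta)
  idx <- match(alignment$seq_id, meta$seq_id)
  if (anyNA(idx))
    stop(path, ": no metadata for: ",
         paste(alignment$seq_id[is.na(idx)], collapse = ", "))
  alignment$locality <- meta$locality[idx]
  alignment$group <- meta$group[idx]
  alignment
}

#' Read occurrence records from CSV
#'
#' Header `site_id,longitude,latitude,elevation_m,site_type,year,infested`.
#'
#' @param path Path to the CSV file.
#' @return An [occurrence_records()] data.frame.
#' @export
read_occurrences <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.character(df$infested))
    df$infested <- toupper(df$infested) %in% c("TRUE", "T", "1", "YES")
  occurrence_records(df)
}

#' Write occurrence records to CSV
#' @param occurrences An [occurrence_records()] data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(occurrences, path) {
  utils::write.csv(as.data.frame(occurrences), path, row.names = FALSE)
  invisible(path)
}

#' Read fruit inspection records from CSV
#' @param path Path to the CSV file (schema of [fruit_records()]).
#' @return A [fruit_records()] data.frame.
#' @export
read_fruit_records <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("moth_stages_present", "silk_threads", "kernel_damaged",
                "sheath_crack"))
    if (col %in% names(df) && is.character(df[[col]]))
      df[[col]] <- toupper(df[[col]]) %in% c("TRUE", "T", "1", "YES")
  fruit_records(df)
}

#' Write fruit records to CSV
#' @param records A [fruit_records()] data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fruit_records <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}

ASC_HEADER_KEYS <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")

#' Read an ESRI ASCII grid
#'
#' Parses the six-line header (`ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize`, optional `NODATA_value`) and the row-major value block
#' (first data row = northernmost). NODATA cells become `NA`.
#'
#' @param path Path to the `.asc` file.
#' @return A [raster_grid()].
#' @export
read_asc_grid <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  hdr <- list()
  data_start <- NA_integer_
  for (i in seq_along(lines)) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) == 2 &&
        tolower(parts[1]) %in% c(ASC_HEADER_KEYS, "nodata_value")) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    } else {
      data_start <- i
      break
    }
  }
  miss <- setdiff(ASC_HEADER_KEYS, names(hdr))
  if (length(miss))
    stop(path, ": ESRI ASCII header missing key(s): ",
         paste(miss, collapse = ", "))
  if (is.na(data_start)) stop(path, ": no data block after the header")
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  vals <- suppressWarnings(
    as.numeric(unlist(strsplit(trimws(lines[data_start:length(lines)]),
                               "\\s+"))))
  vals <- vals[!is.na(vals) | rep(TRUE, length(vals))]
  if (length(vals) != nr * nc)
    stop(sprintf("%s: expected %d values (%d x %d), found %d",
                 path, nr * nc, nr, nc, length(vals)))
  m <- matrix(vals, nr, nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  grid <- grid_spec(hdr$xllcorner, hdr$xllcorner + nc * hdr$cellsize,
                    hdr$yllcorner, hdr$yllcorner + nr * hdr$cellsize,
                    hdr$cellsize)
  raster_grid(grid, m)
}

#' Write a raster or score surface as an ESRI ASCII grid
#'
#' @param x A [raster_grid()] or `score_surface` (masked cells written as
#'   NODATA).
#' @param path Output path.
#' @param nodata NODATA sentinel (default -9999).
#' @return `path`, invisibly.
#' @export
write_asc_grid <- function(x, path, nodata = -9999) {
  if (inherits(x, "score_surface")) {
    m <- x$scores
    m[!x$mask] <- NA_real_
    grid <- x$grid
  } else if (inherits(x, "raster_grid")) {
    m <- x$values
    grid <- x$grid
  } else stop("x must be a raster_grid or score_surface")
  hdr <- c(sprintf("ncols %d", grid$n_cols),
           sprintf("nrows %d", grid$n_rows),
           sprintf("xllcorner %.10g", grid$min_lon),
           sprintf("yllcorner %.10g", grid$min_lat),
           sprintf("cellsize %.10g", grid$cell_size),
           sprintf("NODATA_value %g", nodata))
  m[is.na(m)] <- nodata
  rows <- apply(m, 1, function(r) paste(format(r, trim = TRUE,
                                               scientific = FALSE),
                                        collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}
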