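#' Read a FASTA file into a sequence record table
#'
#' Sequence records are kept as a plain data frame with one row per sequence:
#' `id` (FASTA header token up to the first whitespace), `residues`
#' (upper-cased IUPAC DNA, gaps retained), `length` (number of non-gap
#' characters), and the specimen metadata columns `taxon_group`, `station_id`
#' and `morpho_label`, left `NA` until joined with a metadata table.
#'
#' @param path Path to a FASTA file.
#' @return A data frame of sequence records in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  res <- toupper(as.character(set))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  empty <- nchar(gsub("-", "", res)) == 0L
  if (any(empty)) stop("empty sequence for record(s): ",
                       paste(ids[empty], collapse = ", "))
  bad <- grepl("[^ACGTRYSWKMBDHVN.-]", res)
  if (any(bad)) stop("non-IUPAC characters in record(s): ",
                     paste(ids[bad], collapse = ", "))
  seq_records(ids, res)
}

#' Construct a sequence record table
#'
#' @param id Character vector of unique sequence ids.
#' @param residues Upper-case IUPAC DNA strings (gaps allowed).
#' @param taxon_group,station_id,morpho_label Optional per-sequence metadata.
#' @return A data frame of sequence records.
#' @export
seq_records <- function(id, residues, taxon_group = NA_character_,
                        station_id = NA_character_,
                        morpho_label = NA_character_) {
  stopifnot(length(id) == length(residues))
  if (anyDuplicated(id)) stop("sequence ids must be unique")
  if (length(id) == 0L) {
    return(data.frame(id = character(), residues = character(),
                      length = integer(), taxon_group = character(),
                      station_id = character(), morpho_label = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    id = as.character(id),
    residues = toupper(as.character(residues)),
    length = nchar(gsub("-", "", residues)),
    taxon_group = taxon_group,
    station_id = station_id,
    morpho_label = morpho_label,
    stringsAsFactors = FALSE
  )
}

#' Write sequence records to FASTA
#'
#' @param records A sequence record table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  writeLines(paste0(">", records$id, "\n", records$residues), path)
  invisible(path)
}

#' Read the station table
#'
#' Expects a delimited file (TSV, or CSV by file extension) with columns
#' `station_id`, `license_area`, `latitude`, `longitude`, `depth_m`.
#' Longitudes west of Greenwich are negative.
#'
#' @param path Path to the delimited station table.
#' @return A data frame of stations.
#' @export
read_station_table <- function(path) {
  if (!file.exists(path)) stop("station table not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("station_id", "license_area", "latitude", "longitude", "depth_m")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("station table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(tab) == 0L) return(tab[, need])
  for (col in c("latitude", "longitude", "depth_m")) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v) & !is.na(tab[[col]]))
    if (length(bad)) stop("non-numeric ", col, " in station table row(s): ",
                          paste(bad, collapse = ", "))
    tab[[col]] <- v
  }
  validate_stations(tab[, need])
}

validate_stations <- function(tab) {
  if (anyDuplicated(tab$station_id)) stop("duplicate station ids")
  if (any(tab$latitude < -90 | tab$latitude > 90, na.rm = TRUE))
    stop("latitude out of [-90, 90]")
  if (any(tab$longitude < -180 | tab$longitude > 180, na.rm = TRUE))
    stop("longitude out of [-180, 180]")
  if (any(tab$depth_m <= 0, na.rm = TRUE)) stop("depth must be positive")
  tab
}

#' Read a per-sequence metadata table and join it onto records
#'
#' The metadata table needs columns `id`, `taxon_group`, `station_id` and
#' (optionally) `morpho_label`; the join key is the FASTA header token up to
#' the first whitespace.
#'
#' @param records A sequence record table from [read_fasta()].
#' @param path Path to a TSV/CSV metadata table.
#' @return The record table with metadata columns filled.
#' @export
join_metadata <- function(records, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  meta <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE)
  need <- c("id", "taxon_group", "station_id")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("metadata table missing column(s): ",
                         paste(miss, collapse = ", "))
  i <- match(records$id, meta$id)
  if (anyNA(i)) warning(sum(is.na(i)), " record(s) without metadata")
  records$taxon_group <- meta$taxon_group[i]
  records$station_id <- meta$station_id[i]
  records$morpho_label <-
    if ("morpho_label" %in% names(meta)) meta$morpho_label[i] else NA_character_
  records
}

#' Screen sequences for pseudogene-like stop codons
#'
#' Each sequence is translated (gaps removed) in all three forward frames
#' under the given genetic code; a record passes if at least one frame is
#' free of internal stop codons. Reverse frames are not tried since COI
#' amplicons have fixed primer orientation.
#'
#' @param records A sequence record table.
#' @param genetic_code NCBI translation table id; default `"5"`
#'   (invertebrate mitochondrial).
#' @return A list with elements `pass` (record table) and `fail` (record
#'   table with `reason` and per-frame internal stop counts).
#' @export
screen_pseudogenes <- function(records, genetic_code = "5") {
  code <- Biostrings::getGeneticCode(genetic_code)
  n <- nrow(records)
  keep <- logical(n)
  reason <- character(n)
  stops <- matrix(NA_integer_, n, 3,
                  dimnames = list(NULL, paste0("stops_frame", 1:3)))
  for (i in seq_len(n)) {
    s <- gsub("-", "", records$residues[i])
    if (nchar(s) < 3L) {
      reason[i] <- "shorter than one codon"
      next
    }
    for (f in 1:3) {
      sub <- substr(s, f, nchar(s))
      len <- nchar(sub) - nchar(sub) %% 3L
      if (len < 3L) { stops[i, f] <- NA_integer_; next }
      aa <- suppressWarnings(as.character(Biostrings::translate(
        Biostrings::DNAString(substr(sub, 1L, len)),
        genetic.code = code, if.fuzzy.codon = "solve")))
      internal <- substr(aa, 1L, nchar(aa) - 1L)
      stops[i, f] <- lengths(regmatches(internal, gregexpr("\\*", internal)))
    }
    if (any(stops[i, ] == 0L, na.rm = TRUE)) keep[i] <- TRUE
    else reason[i] <- "internal stop codon in all forward frames"
  }
  fail <- cbind(records[!keep, , drop = FALSE],
                reason = reason[!keep],
                stops[!keep, , drop = FALSE])
  rownames(fail) <- NULL
  list(pass = records[keep, , drop = FALSE], fail = fail)
}

#' Read a rooted or unrooted tree from newick
#'
#' @param path Path to a newick file.
#' @param require_lengths Error if branch lengths are absent (UniFrac needs
#'   them); default `TRUE`.
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(path, require_lengths = TRUE) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick in ", path)
  if (require_lengths && is.null(tree$edge.length))
    stop("tree in ", path, " lacks branch lengths")
  tree
}

#' Write a tree to newick with high-precision branch lengths
#'
#' @param tree An [ape::phylo] tree.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}
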