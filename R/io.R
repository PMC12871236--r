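# File formats: structure files ("id<TAB>dotbracket"), FASTA via Biostrings
# (T mapped to U on read), two-column SHAPE reactivity tables, and the TSV
# candidate reports emitted by the design/score drivers.

#' Read a structure file
#'
#' One record per line: \code{id<TAB>dotbracket}.
#'
#' @param path file path.
#' @return named list of \code{secondary_structure}s.
#' @export
read_structure_file <- function(path) {
  if (!file.exists(path)) stop("structure file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) != 2L) stop("malformed structure record: ", ln)
    out[[f[1L]]] <- parse_dotbracket(f[2L])
  }
  out
}

#' Write a structure file
#'
#' @param structures named list of \code{secondary_structure}s.
#' @param path output path.
#' @export
write_structure_file <- function(structures, path) {
  ids <- names(structures)
  if (is.null(ids)) ids <- sprintf("structure_%03d", seq_along(structures))
  writeLines(vapply(seq_along(structures), function(i) {
    paste(ids[i], dotbracket(structures[[i]]), sep = "\t")
  }, character(1)), path)
  invisible(path)
}

#' Read RNA sequences from FASTA
#'
#' Standard \code{>id} headers; DNA-style T/t is mapped to U on read.
#'
#' @param path FASTA file.
#' @return named character vector of ACGU sequences.
#' @export
read_fasta_rna <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  seqs <- chartr("Tt", "Uu", toupper(as.character(set)))
  stats::setNames(seqs, names(set))
}

#' Write RNA sequences to FASTA
#'
#' @param sequences named character vector.
#' @param path output path.
#' @export
write_fasta_rna <- function(sequences, path) {
  ids <- names(sequences)
  if (is.null(ids)) ids <- sprintf("seq_%03d", seq_along(sequences))
  set <- Biostrings::BStringSet(unname(sequences))
  names(set) <- ids
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a SHAPE reactivity table
#'
#' Two whitespace-separated columns: 0-based position, reactivity.
#'
#' @param path table path.
#' @return a \code{shape_profile}.
#' @export
read_shape_table <- function(path) {
  if (!file.exists(path)) stop("SHAPE table not found: ", path)
  tab <- utils::read.table(path, header = FALSE,
                           col.names = c("position", "reactivity"))
  tab <- tab[order(tab$position), ]
  if (!identical(as.integer(tab$position), seq_len(nrow(tab)) - 1L)) {
    stop("SHAPE table positions must be 0-based and contiguous")
  }
  shape_profile(tab$reactivity)
}

#' Write a SHAPE reactivity table
#'
#' @param profile a \code{shape_profile}.
#' @param path output path.
#' @export
write_shape_table <- function(profile, path) {
  utils::write.table(
    data.frame(position = seq_along(profile$reactivities) - 1L,
               reactivity = profile$reactivities),
    path, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

# flatten screened candidates into the report data frame used by the CLI
candidates_report <- function(candidates, target_id) {
  do.call(rbind, lapply(candidates, function(cn) {
    rep <- cn$report %||% list(jaccard = NA_real_, eterna_classic = NA_real_,
                               crossed_pair_quality = NA_real_,
                               openknot = NA_real_)
    data.frame(target_id = target_id, sequence = cn$sequence,
               provenance = cn$provenance, cumulative_q = cn$cumulative_q,
               jaccard = rep$jaccard, eterna_classic = rep$eterna_classic,
               crossed_pair_quality = rep$crossed_pair_quality,
               openknot = rep$openknot, stringsAsFactors = FALSE)
  }))
}
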