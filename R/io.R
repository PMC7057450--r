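## Readers and writers: gene-order TSV, ortholog FASTA, reports, manifests.
##
## Gene-order TSV columns: genome_id, position (0-based), gene_id; the rows
## of one genome must cover a contiguous 0..n-1 position range.
## FASTA record ids are "genome_id|gene_id" (delimiter configurable).

#' Ortholog alignment for one gene family
#'
#' Equal-length aligned nucleotide sequences of one gene family across
#' genomes. Simulated or pre-aligned sequences only; no alignment is
#' computed here.
#'
#' @param gene_id Gene-family identifier.
#' @param seqs Named character vector, one sequence per genome id; all the
#'   same length.
#' @return An object of class `ortholog_alignment`: list with `gene_id`,
#'   `seqs`, `n_sites`.
#' @export
ortholog_alignment <- function(gene_id, seqs) {
  if (length(gene_id) != 1L) stop("'gene_id' must be a single string")
  if (length(seqs) < 1L) {
    stop("alignment for gene '", gene_id, "' has no sequences")
  }
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("alignment sequences for gene '", gene_id,
         "' must be named by genome id")
  }
  seqs <- stats::setNames(toupper(as.character(seqs)), names(seqs))
  widths <- nchar(seqs)
  if (any(widths < 1L)) {
    stop("alignment for gene '", gene_id, "' contains an empty sequence")
  }
  if (length(unique(widths)) != 1L) {
    stop("alignment for gene family '", gene_id,
         "' has unequal sequence lengths (",
         paste(unique(widths), collapse = ", "), ")")
  }
  structure(list(gene_id = as.character(gene_id), seqs = seqs,
                 n_sites = widths[[1L]]),
            class = "ortholog_alignment")
}

#' Read circular gene orders from TSV
#'
#' Expects columns `genome_id`, `position` (0-based integer) and `gene_id`.
#' For every genome the positions must be exactly `0..n-1` with no gaps or
#' duplicates, and gene ids must be unique within the genome; violations
#' are reported with the offending genome and rows.
#'
#' @param path TSV file path.
#' @return Named list of [genome()] objects keyed by genome id.
#' @export
read_gene_orders <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("genome_id", "position", "gene_id")
  if (!all(required %in% names(df))) {
    stop("gene-order file '", path, "' must have columns ",
         paste(required, collapse = ", "))
  }
  if (nrow(df) == 0L) stop("gene-order file '", path, "' is empty")
  df$position <- suppressWarnings(as.integer(df$position))
  if (anyNA(df$position)) {
    bad <- which(is.na(df$position))[1L]
    stop("non-integer position in '", path, "' at data row ", bad)
  }
  df$.row <- seq_len(nrow(df))
  genomes <- list()
  for (gid in unique(df$genome_id)) {
    sub <- df[df$genome_id == gid, , drop = FALSE]
    n <- nrow(sub)
    dup_pos <- sub$position[duplicated(sub$position)]
    if (length(dup_pos) > 0L) {
      stop("genome '", gid, "' has duplicated position ", dup_pos[1L],
           " (data rows ",
           paste(sub$.row[sub$position == dup_pos[1L]], collapse = ", "), ")")
    }
    if (!setequal(sub$position, 0:(n - 1L))) {
      missing <- setdiff(0:(n - 1L), sub$position)
      stop("genome '", gid, "' positions are not a contiguous 0..", n - 1L,
           " range (missing: ", paste(utils::head(missing, 5L),
                                      collapse = ", "), ")")
    }
    dup_gene <- unique(sub$gene_id[duplicated(sub$gene_id)])
    if (length(dup_gene) > 0L) {
      stop("genome '", gid, "' has duplicated gene_id '", dup_gene[1L],
           "' (data rows ",
           paste(sub$.row[sub$gene_id == dup_gene[1L]], collapse = ", "),
           ")")
    }
    sub <- sub[order(sub$position), , drop = FALSE]
    genomes[[gid]] <- genome(gid, sub$gene_id)
  }
  genomes
}

#' Write gene orders as TSV
#'
#' @param genomes Named list of [genome()] objects.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_gene_orders <- function(genomes, path) {
  rows <- lapply(genomes, function(g) {
    data.frame(genome_id = g$genome_id,
               position = seq_along(g$genes) - 1L,
               gene_id = g$genes, stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), file = path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read ortholog alignments from FASTA
#'
#' Record ids must be `genome_id<delim>gene_id`. Records are grouped by gene
#' id into per-family alignments; sequences within a family must have equal
#' lengths. Lowercase sequences are accepted and upcased.
#'
#' @param path FASTA file path (one combined file, or call per family file).
#' @param delim Single-character delimiter inside record ids (default `"|"`).
#' @return Named list of [ortholog_alignment()] objects keyed by gene id.
#' @export
read_alignments <- function(path, delim = "|") {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("FASTA file '", path, "' contains no records")
  ids <- names(ss)
  parts <- strsplit(ids, delim, fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) != 2L)
  if (length(bad) > 0L) {
    stop("malformed FASTA record id '", ids[bad[1L]],
         "': expected genome_id", delim, "gene_id")
  }
  genome_id <- vapply(parts, `[`, character(1), 1L)
  gene_id <- vapply(parts, `[`, character(1), 2L)
  seqs <- as.character(ss)
  out <- list()
  for (g in unique(gene_id)) {
    sel <- gene_id == g
    out[[g]] <- ortholog_alignment(g, stats::setNames(seqs[sel],
                                                      genome_id[sel]))
  }
  out
}

#' Write ortholog alignments as FASTA
#'
#' @param alignments Named list of [ortholog_alignment()] objects.
#' @param path Output file path.
#' @param delim Delimiter between genome and gene id in record ids.
#' @return The path, invisibly.
#' @export
write_alignments <- function(alignments, path, delim = "|") {
  ids <- character(0); seqs <- character(0)
  for (aln in alignments) {
    ids <- c(ids, paste0(names(aln$seqs), delim, aln$gene_id))
    seqs <- c(seqs, unname(aln$seqs))
  }
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- ids
  Biostrings::writeXStringSet(ss, filepath = path)
  invisible(path)
}

#' Write a simulated quartet to a directory
#'
#' Writes `orders.tsv` (gene orders of the four genomes), `sequences.fasta`
#' (per-gene copies across the quartet) and `truth.txt` (one rearranged gene
#' id per line).
#'
#' @param q A `sim_quartet` from [simulate_quartet()].
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_quartet <- function(q, dir) {
  if (!inherits(q, "sim_quartet")) stop("'q' must be a sim_quartet")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_gene_orders(quartet_genomes(q), file.path(dir, "orders.tsv"))
  write_alignments(quartet_alignments(q), file.path(dir, "sequences.fasta"))
  writeLines(q$truth, file.path(dir, "truth.txt"))
  invisible(dir)
}

#' Write a run manifest
#'
#' Records the configuration, input checksums, seed and package version of a
#' run next to its report, so the run can be reproduced bit-identically.
#'
#' @param path Output JSON path.
#' @param config Named list of resolved run parameters.
#' @param inputs Character vector of input file paths (checksummed with
#'   MD5).
#' @param seed Integer seed used, or `NULL`.
#' @return The path, invisibly.
#' @export
write_manifest <- function(path, config, inputs = character(0), seed = NULL) {
  inputs <- inputs[file.exists(inputs)]
  manifest <- list(
    tool = "sihgt",
    version = as.character(utils::packageVersion("sihgt")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    inputs = as.list(stats::setNames(unname(tools::md5sum(inputs)),
                                     inputs)))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}
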