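# Format handlers. All genomic coordinates in memory are 0-based half-open;
# the on-disk formats keep their native conventions (BED is already 0-based
# half-open, refFlat/genePred likewise for txStart/exonStarts).

#' Read a (possibly gzipped) FASTA file
#'
#' Headers are truncated at the first whitespace.
#' @param path FASTA file, plain or gzip-compressed.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  out <- as.character(set)
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Write sequences to FASTA
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  genome <- as_genome(genome)
  set <- Biostrings::DNAStringSet(unname(genome))
  names(set) <- names(genome)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write pG4 hits as BED6
#'
#' Columns: chrom, start, end, name (`pG4_<i>`), score (Q-score or 0),
#' strand.
#' @param hits Hits data frame from [scan_genome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, path) {
  score <- hits$q_score
  if (is.null(score)) score <- rep(NA_real_, nrow(hits))
  score[!is.finite(score)] <- 0
  bed <- data.frame(chrom = hits$chrom, start = hits$start, end = hits$end,
                    name = sprintf("pG4_%d", seq_len(nrow(hits))),
                    score = score, strand = hits$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 file of pG4 hits
#'
#' The score column is taken as a Q-score; 0 means "no score".
#' @param path BED file (>= 6 columns).
#' @return Hits data frame (`chrom`, `start`, `end`, `strand`, `name`,
#'   `q_score`).
#' @export
read_hits_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 6L) stop("BED6 required: ", path, " has ", ncol(bed),
                           " columns")
  data.frame(chrom = as.character(bed[[1L]]), start = as.integer(bed[[2L]]),
             end = as.integer(bed[[3L]]), strand = as.character(bed[[6L]]),
             name = as.character(bed[[4L]]),
             q_score = ifelse(bed[[5L]] == 0, NA_real_,
                              as.numeric(bed[[5L]])),
             stringsAsFactors = FALSE)
}

parse_ucsc_list <- function(x) {
  lapply(strsplit(sub(",$", "", x), ","), as.integer)
}

#' Read gene models from a refFlat / genePred file
#'
#' Accepts both the 11-column refFlat dialect (geneName, name, chrom,
#' strand, txStart, txEnd, cdsStart, cdsEnd, exonCount, exonStarts,
#' exonEnds) and the 10-column genePred dialect without the leading
#' geneName. Comma-terminated exon lists are handled. `cdsStart == cdsEnd`
#' marks a noncoding transcript.
#'
#' @param path Tab-separated refFlat/genePred file (no header).
#' @return A gene-model data frame (see [gene_models()]).
#' @export
read_refflat <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(tab) == 11L) {
    gene_id <- as.character(tab[[1L]]); off <- 1L
  } else if (ncol(tab) == 10L) {
    gene_id <- as.character(tab[[1L]]); off <- 0L
  } else {
    stop("expected 10 (genePred) or 11 (refFlat) columns, got ", ncol(tab))
  }
  gene_models(gene_id = gene_id,
              transcript_id = as.character(tab[[1L + off]]),
              chrom = as.character(tab[[2L + off]]),
              strand = as.character(tab[[3L + off]]),
              tx_start = as.integer(tab[[4L + off]]),
              tx_end = as.integer(tab[[5L + off]]),
              cds_start = as.integer(tab[[6L + off]]),
              cds_end = as.integer(tab[[7L + off]]),
              exon_starts = parse_ucsc_list(tab[[9L + off]]),
              exon_ends = parse_ucsc_list(tab[[10L + off]]))
}

#' Write gene models in refFlat layout
#' @param models Gene-model data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_refflat <- function(models, path) {
  lines <- vapply(seq_len(nrow(models)), function(i) {
    paste(models$gene_id[i], models$transcript_id[i], models$chrom[i],
          models$strand[i], models$tx_start[i], models$tx_end[i],
          models$cds_start[i], models$cds_end[i],
          length(models$exon_starts[[i]]),
          paste0(paste(models$exon_starts[[i]], collapse = ","), ","),
          paste0(paste(models$exon_ends[[i]], collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read EST start-site records
#'
#' Expects a tab-separated file with header columns `chrom`, `strand`,
#' `start_site` (0-based genomic position of the transcript 5' end).
#' @param path TSV path.
#' @return Data frame of EST records.
#' @export
read_est_tsv <- function(path) {
  est <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("chrom", "strand", "start_site")
  if (!all(need %in% names(est))) {
    stop("EST TSV needs columns: ", paste(need, collapse = ", "))
  }
  est
}

#' Read an expression matrix with sample metadata
#'
#' The matrix file is TSV with the gene id in the first column and sample
#' ids in the header; the metadata file is TSV with columns `sample`,
#' `tissue`, `condition` (normal/tumor) and `patient`.
#' @param matrix_path,meta_path File paths.
#' @return An [expression_matrix()] object.
#' @export
read_expression_tsv <- function(matrix_path, meta_path) {
  tab <- utils::read.table(matrix_path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(values) <- as.character(tab[[1L]])
  meta <- utils::read.table(meta_path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  expression_matrix(values, meta)
}

#' Write an expression matrix and its metadata
#' @param m [expression_matrix()] object.
#' @param matrix_path,meta_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_expression_tsv <- function(m, matrix_path, meta_path) {
  tab <- data.frame(gene = rownames(m$values), m$values,
                    check.names = FALSE)
  utils::write.table(tab, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(m$meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(matrix_path, meta_path))
}

#' Read a mutation catalog
#'
#' TSV with header columns `chrom`, `pos` (0-based), `ref`, `alt`,
#' `mut_type` (substitution/deletion/insertion/duplication), `source`
#' (germline/somatic), `label` and `sample_id` (somatic only; may be
#' empty for germline records).
#' @param path TSV path.
#' @return Mutation data frame.
#' @export
read_mutations_tsv <- function(path) {
  mut <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "")
  need <- c("chrom", "pos", "ref", "alt", "mut_type", "source", "label")
  if (!all(need %in% names(mut))) {
    stop("mutation TSV needs columns: ", paste(need, collapse = ", "))
  }
  if (is.null(mut$sample_id)) mut$sample_id <- NA_character_
  mut
}

#' Read / write a pipeline configuration in YAML
#' @param path YAML path.
#' @return For `read_config_yaml`, the configuration list.
#' @export
read_config_yaml <- function(path) yaml::read_yaml(path)

#' @rdname read_config_yaml
#' @param config Configuration list.
#' @export
write_config_yaml <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
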