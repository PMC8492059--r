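#' Read a multi-sample biallelic VCF into a genotype matrix
#'
#' Parses GT fields into diploid dosages (0/1/2, NA for missing), and reads
#' the SV annotations: `SVTYPE` from INFO or a symbolic ALT, `SVLEN` from
#' INFO (magnitude stored; deletions may be negative in the file), falling
#' back to the REF/ALT length difference for sequence-resolved records.
#' Unknown SV types are kept as "other"; records without SV annotation are
#' typed "SNP".
#'
#' @param path VCF file (plain or bgzipped)
#' @return genotype_matrix.
#' @export
read_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  info_field <- function(info, key) {
    pat <- paste0("(?:^|;)", key, "=([^;]+)")
    has <- !is.na(info) & grepl(pat, info, perl = TRUE)
    out <- rep(NA_character_, length(info))
    out[has] <- sub(paste0(".*(?:^|;)", key, "=([^;]+).*"), "\\1",
                    info[has], perl = TRUE)
    out
  }
  svtype <- info_field(fix$INFO, "SVTYPE")
  svlen <- suppressWarnings(as.numeric(info_field(fix$INFO, "SVLEN")))
  sym <- grepl("^<.+>$", fix$ALT)
  svtype[is.na(svtype) & sym] <- gsub("[<>]", "", fix$ALT[is.na(svtype) & sym])
  known <- c("INS", "DEL", "INV", "DUP")
  svtype[!is.na(svtype) & !(svtype %in% known)] <- "other"
  seqlen <- abs(nchar(fix$ALT) - nchar(fix$REF))
  svlen[is.na(svlen)] <- seqlen[is.na(svlen)]
  svtype[is.na(svtype)] <- "SNP"
  ids <- fix$ID
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix$CHROM[noid], "_", fix$POS[noid])
  variants <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                         id = ids, ref = fix$REF, alt = fix$ALT,
                         svtype = svtype, svlen = as.integer(abs(svlen)),
                         stringsAsFactors = FALSE)
  alleles <- function(x) {
    x <- sub(":.*", "", x)
    ifelse(x %in% c(".", "./.", ".|."), NA_integer_,
           vapply(strsplit(x, "[/|]"), function(a) {
             a <- suppressWarnings(as.integer(a))
             if (anyNA(a)) NA_integer_ else sum(a)
           }, integer(1)))
  }
  d <- apply(gt, 2L, alleles)
  if (is.null(dim(d))) d <- matrix(d, nrow = 1L, dimnames = list(NULL, colnames(gt)))
  dos <- t(d)
  colnames(dos) <- variants$id
  genotype_matrix(variants, dos)
}

#' Write a genotype matrix as a plain-text VCF 4.2 file
#'
#' Emits biallelic records with GT fields. SV records get `SVTYPE` and
#' `SVLEN` INFO keys, with the conventional negative SVLEN for deletions.
#'
#' @param gm genotype_matrix
#' @param path output path
#' @return invisibly, the path.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  v <- gm$variants
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=svadapt",
               '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV type">',
               '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="SV length">',
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  samples <- rownames(gm$dosages)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"), con)
  gt_of <- c("0/0", "0/1", "1/1")
  for (j in seq_len(nrow(v))) {
    info <- if (v$svtype[j] %in% c("INS", "DEL", "INV", "DUP", "other")) {
      slen <- if (v$svtype[j] == "DEL") -abs(v$svlen[j]) else abs(v$svlen[j])
      sprintf("SVTYPE=%s;SVLEN=%d", v$svtype[j], slen)
    } else "."
    gts <- gm$dosages[, j]
    gt <- ifelse(is.na(gts), "./.", gt_of[gts + 1L])
    writeLines(paste(c(v$chrom[j], v$pos[j], v$id[j], v$ref[j], v$alt[j],
                       ".", "PASS", info, "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a sample-to-population map TSV
#'
#' Expects columns `sample_id`, `population`, optionally `superpopulation`
#' and `admixed` (0/1 or logical).
#'
#' @param path TSV file with a header line
#' @return popmap.
#' @export
read_popmap <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "population") %in% names(x)))
    stop("popmap needs sample_id and population columns")
  population_map(x$sample_id, x$population,
                 superpopulation = x$superpopulation %||% x$population,
                 admixed = as.logical(x$admixed %||% FALSE))
}

#' Write a population map TSV
#' @param popmap popmap
#' @param path output path
#' @return invisibly, the path.
#' @export
write_popmap <- function(popmap, path) {
  utils::write.table(popmap, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a putative-introgressed-marker table
#'
#' TSV with columns `chrom`, `pos` (1-based) and optionally `allele`,
#' `population`, `score` (the layout produced by haplotype-based archaic
#' introgression scans). Rows are sorted by chromosome and position.
#'
#' @param path TSV file with a header line
#' @return data.frame of markers.
#' @export
read_markers <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("chrom", "pos") %in% names(x)))
    stop("marker table needs chrom and pos columns")
  x[order(x$chrom, x$pos), , drop = FALSE]
}

#' Read a BED mask (0-based half-open intervals)
#'
#' @param path BED file (first three columns used)
#' @return data.frame: `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  x <- utils::read.table(path, stringsAsFactors = FALSE)
  if (ncol(x) < 3L) stop("malformed BED: fewer than 3 columns")
  out <- data.frame(chrom = x[[1L]], start = as.integer(x[[2L]]),
                    end = as.integer(x[[3L]]), stringsAsFactors = FALSE)
  if (any(is.na(out$start) | is.na(out$end)) || any(out$end < out$start))
    stop("malformed BED intervals")
  out
}

#' Read sequences from a FASTA or FASTQ file
#'
#' @param path sequence file; format inferred from the extension
#'   (.fq/.fastq = FASTQ, else FASTA)
#' @return named character vector of sequences.
#' @export
read_fastx <- function(path) {
  fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path)) "fastq" else "fasta"
  x <- Biostrings::readDNAStringSet(path, format = fmt)
  stats::setNames(as.character(x), names(x))
}

#' Write reads as FASTQ with uniform dummy qualities
#'
#' @param reads named character vector of sequences
#' @param path output path
#' @return invisibly, the path.
#' @export
write_fastq <- function(reads, path) {
  ids <- names(reads) %||% sprintf("read_%d", seq_along(reads))
  lines <- as.vector(rbind(paste0("@", ids), unname(reads), "+",
                           vapply(nchar(reads),
                                  function(n) strrep("I", n), character(1))))
  writeLines(lines, path)
  invisible(path)
}

#' Write a data.frame as a TSV with stable formatting
#'
#' Numeric columns are rendered at 6 significant digits so that reruns are
#' byte-identical.
#'
#' @param x data.frame
#' @param path output path
#' @return invisibly, the path.
#' @export
write_tsv <- function(x, path) {
  y <- as.data.frame(x)
  for (j in seq_along(y))
    if (is.numeric(y[[j]]) && !is.integer(y[[j]]))
      y[[j]] <- signif(y[[j]], 6)
  utils::write.table(y, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
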