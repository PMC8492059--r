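#' Tag candidate archaic-introgressed structural variants
#'
#' A differentiated SV is called a candidate for archaic introgression when
#' it is in moderate LD (r-squared above `min_r2`) with at least one
#' putative introgressed marker within `window_bp`, while remaining rare
#' (pooled allele frequency below `outgroup_max_af`) in the non-admixed
#' outgroup populations. LD is computed in a single focal population chosen
#' to match the SV's ancestry component.
#'
#' @param sv_ids ids of the differentiated SVs to test
#' @param markers data.frame with columns `chrom`, `pos` (1-based) and
#'   optionally `allele`, `population`, `score` (positions are matched to
#'   variants in `gm`)
#' @param gm genotype_matrix holding both the SVs and the marker variants
#' @param popmap popmap
#' @param focal_pop population in which LD is computed: a single label or a
#'   named vector keyed by SV id (the component-to-population mapping)
#' @param window_bp marker search window half-width (default 1e5)
#' @param min_r2 LD threshold (default 0.5)
#' @param outgroup_max_af outgroup rarity threshold (default 0.01)
#' @param outgroup_pops populations pooled as the outgroup; default: all
#'   populations flagged non-admixed in `popmap` whose superpopulation is
#'   `outgroup_superpop`
#' @param outgroup_superpop default outgroup superpopulation label ("AFR")
#' @param excluded_pops populations excluded from the outgroup pool even if
#'   they match (default c("ASW", "ACB"), the admixed African-ancestry
#'   cohorts)
#' @return data.frame: `sv_id`, `population`, `best_marker`, `r2`,
#'   `outgroup_af`, `candidate`, `reason` (NA when a candidate; otherwise
#'   "no_marker_in_window", "low_ld" or "outgroup_af").
#' @export
tag_candidates <- function(sv_ids, markers, gm, popmap, focal_pop,
                           window_bp = 1e5, min_r2 = 0.5,
                           outgroup_max_af = 0.01, outgroup_pops = NULL,
                           outgroup_superpop = "AFR",
                           excluded_pops = c("ASW", "ACB")) {
  stopifnot(inherits(gm, "genotype_matrix"))
  v <- gm$variants
  if (is.null(outgroup_pops)) {
    og <- unique(popmap$population[popmap$superpopulation ==
                                     outgroup_superpop & !popmap$admixed])
    outgroup_pops <- setdiff(og, excluded_pops)
  } else {
    outgroup_pops <- setdiff(outgroup_pops, excluded_pops)
  }
  if (length(outgroup_pops) == 0L) stop("no outgroup populations available")
  og_samples <- popmap$sample_id[popmap$population %in% outgroup_pops]
  og_idx <- match(og_samples, rownames(gm$dosages))
  pops <- pop_sample_index(gm, popmap)
  # markers present in the genotype matrix, by coordinate
  mk_idx <- match(paste(markers$chrom, markers$pos),
                  paste(v$chrom, v$pos))
  markers <- markers[!is.na(mk_idx), , drop = FALSE]
  mk_idx <- mk_idx[!is.na(mk_idx)]
  rows <- lapply(sort(sv_ids), function(sv) {
    fi <- match(sv, v$id)
    if (is.na(fi)) stop("unknown SV id: ", sv)
    pop <- if (length(focal_pop) > 1L || !is.null(names(focal_pop)))
      focal_pop[[sv]] else focal_pop
    if (!pop %in% names(pops)) stop("focal population not in popmap: ", pop)
    d_og <- gm$dosages[og_idx, fi]
    og_af <- if (all(is.na(d_og))) NA_real_
             else sum(d_og, na.rm = TRUE) / (2 * sum(!is.na(d_og)))
    near <- which(markers$chrom == v$chrom[fi] &
                    abs(markers$pos - v$pos[fi]) <= window_bp &
                    mk_idx != fi)
    if (length(near) == 0L) {
      return(data.frame(sv_id = sv, population = pop,
                        best_marker = NA_character_, r2 = NA_real_,
                        outgroup_af = og_af, candidate = FALSE,
                        reason = "no_marker_in_window",
                        stringsAsFactors = FALSE))
    }
    idx <- pops[[pop]]
    gf <- gm$dosages[idx, fi]
    r2s <- vapply(mk_idx[near], function(mi) {
      r <- try(ld_r2(gf, gm$dosages[idx, mi]), silent = TRUE)
      if (inherits(r, "try-error")) NA_real_ else as.numeric(r)
    }, numeric(1))
    # deterministic argmax irrespective of marker order: break ties on the
    # marker's genomic position
    ord <- order(-r2s, v$pos[mk_idx[near]], na.last = TRUE)
    best <- ord[1L]
    r2_best <- r2s[best]
    cand <- isTRUE(r2_best > min_r2) && isTRUE(og_af < outgroup_max_af)
    reason <- if (cand) NA_character_
              else if (!isTRUE(r2_best > min_r2)) "low_ld" else "outgroup_af"
    data.frame(sv_id = sv, population = pop,
               best_marker = v$id[mk_idx[near][best]], r2 = r2_best,
               outgroup_af = og_af, candidate = cand, reason = reason,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Allele matching between archaic read profiles and a modern haplotype
#'
#' For each archaic sample, calls the alternative allele at a site when at
#' least `min_reads` aligned reads support it, and counts the sites where
#' that call equals the allele defining the differentiated modern
#' haplotype.
#'
#' @param hap_alleles named integer vector (site id -> 0/1), the
#'   haplotype-defining allele per site (1 = alternative)
#' @param profiles named list: per archaic sample, a named integer vector
#'   of alternative-supporting read counts per site
#' @param min_reads minimum supporting reads to call the alternative
#'   (default 2)
#' @return data.frame: `sample`, `n_sites`, `n_match`, `fraction`,
#'   `percent` (rounded to integer percent, the conventional reporting).
#' @export
archaic_allele_matching <- function(hap_alleles, profiles, min_reads = 2) {
  if (length(hap_alleles) == 0L) stop("zero scored sites")
  rows <- lapply(names(profiles), function(sm) {
    counts <- profiles[[sm]]
    shared <- intersect(names(hap_alleles), names(counts))
    if (length(shared) == 0L) stop("zero scored sites for sample ", sm)
    call <- as.integer(counts[shared] >= min_reads)
    n_match <- sum(call == hap_alleles[shared])
    data.frame(sample = sm, n_sites = length(shared), n_match = n_match,
               fraction = n_match / length(shared),
               percent = round(100 * n_match / length(shared)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Build a breakpoint-spanning diagnostic sequence
#'
#' Concatenates an upstream flank, the inserted sequence and a downstream
#' flank into a single query that occurs only on the insertion-carrying
#' haplotype, recording the component lengths. The canonical use is an
#' 11 bp + 33 bp + 4 bp = 48 bp query for a short insertion, allowing exact
#' string matching against raw reads.
#'
#' @param up_flank,insertion,down_flank nucleotide strings (A/C/G/T;
#'   `insertion` may be empty)
#' @return list of class `diagnostic_kmer`: `sequence`, `up_flank_len`,
#'   `insertion_len`, `down_flank_len`.
#' @export
build_diagnostic_kmer <- function(up_flank, insertion, down_flank) {
  for (s in c(up_flank, insertion, down_flank))
    if (nchar(s) > 0 && grepl("[^ACGT]", s))
      stop("invalid nucleotide characters (A/C/G/T only)")
  structure(list(sequence = paste0(up_flank, insertion, down_flank),
                 up_flank_len = nchar(up_flank),
                 insertion_len = nchar(insertion),
                 down_flank_len = nchar(down_flank)),
            class = "diagnostic_kmer")
}

#' @export
print.diagnostic_kmer <- function(x, ...) {
  cat("diagnostic_kmer:", nchar(x$sequence), "bp (",
      x$up_flank_len, "+", x$insertion_len, "+", x$down_flank_len, ")\n")
  cat(" ", x$sequence, "\n")
  invisible(x)
}

#' Scan reads for exact matches to a diagnostic sequence
#'
#' Counts unique reads (exact sequence deduplication) containing the
#' diagnostic sequence as an exact substring. Matching is forward-strand
#' only by default, mirroring stranded extraction of aligned reads; the
#' both-strand mode also accepts a match to the reverse complement.
#'
#' @param reads character vector of read sequences, or a
#'   `Biostrings::DNAStringSet`, or a path to a FASTA/FASTQ file
#' @param kmer diagnostic_kmer (or a plain string)
#' @param both_strands also match the reverse complement (default FALSE)
#' @return list: `n_match` (unique reads containing the query), `carrier`
#'   (n_match >= 1), `n_reads`, `n_unique_reads`.
#' @export
scan_reads <- function(reads, kmer, both_strands = FALSE) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- read_fastx(reads)
  if (methods::is(reads, "XStringSet")) reads <- as.character(reads)
  query <- if (inherits(kmer, "diagnostic_kmer")) kmer$sequence else kmer
  uniq <- unique(unname(reads))
  hit <- grepl(query, uniq, fixed = TRUE)
  if (both_strands) {
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(query)))
    hit <- hit | grepl(rc, uniq, fixed = TRUE)
  }
  n <- sum(hit)
  list(n_match = n, carrier = n >= 1L, n_reads = length(reads),
       n_unique_reads = length(uniq))
}
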