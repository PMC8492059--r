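#' Genotype matrix container
#'
#' Bundles a variant table with a samples x variants diploid dosage matrix.
#' Dosages take values 0, 1, 2 (count of alternative alleles) or NA for a
#' failed genotype. Variants are biallelic; structural variants carry a type
#' tag and a positive length magnitude (the VCF writer restores the negative
#' SVLEN convention for deletions).
#'
#' @param variants data.frame with columns `chrom`, `pos` (1-based), `id`,
#'   `ref`, `alt`, `svtype` (one of "INS","DEL","INV","DUP","other","SNP"),
#'   `svlen` (non-negative magnitude in bp; 0 for SNPs).
#' @param dosages integer matrix, samples in rows, variants in columns;
#'   `colnames` must equal `variants$id`, `rownames` are sample ids.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `variants` and `dosages`.
#' @examples
#' v <- data.frame(chrom = "chr1", pos = 100L, id = "sv1", ref = "A",
#'                 alt = "<DEL>", svtype = "DEL", svlen = 135L)
#' g <- matrix(c(0L, 1L, 2L), ncol = 1,
#'             dimnames = list(c("s1", "s2", "s3"), "sv1"))
#' gm <- genotype_matrix(v, g)
#' @export
genotype_matrix <- function(variants, dosages) {
  required <- c("chrom", "pos", "id", "ref", "alt", "svtype", "svlen")
  missing_cols <- setdiff(required, names(variants))
  if (length(missing_cols) > 0L)
    stop("variants is missing columns: ", paste(missing_cols, collapse = ", "))
  if (!is.matrix(dosages))
    dosages <- as.matrix(dosages)
  if (ncol(dosages) != nrow(variants))
    stop("dosages has ", ncol(dosages), " columns but variants has ",
         nrow(variants), " rows")
  if (is.null(colnames(dosages)))
    colnames(dosages) <- variants$id
  if (ncol(dosages) > 0L &&
      !identical(colnames(dosages), as.character(variants$id)))
    stop("colnames(dosages) must match variants$id")
  if (anyDuplicated(variants$id))
    stop("duplicated variant ids")
  if (any(variants$pos < 1L))
    stop("positions must be 1-based (>= 1)")
  bad <- dosages[!is.na(dosages) & !(dosages %in% c(0L, 1L, 2L))]
  if (length(bad) > 0L)
    stop("dosages must be 0, 1, 2 or NA")
  variants$id <- as.character(variants$id)
  storage.mode(dosages) <- "integer"
  structure(list(variants = variants, dosages = dosages),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosages), "samples x",
      nrow(x$variants), "variants\n")
  cat("  svtype:", paste(names(table(x$variants$svtype)),
                         table(x$variants$svtype), collapse = ", "), "\n")
  miss <- mean(is.na(x$dosages))
  cat(sprintf("  missingness: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Subset a genotype matrix
#'
#' @param x genotype_matrix
#' @param samples sample index or names (default all)
#' @param variants variant index or ids (default all)
#' @param ... unused
#' @return genotype_matrix restricted to the requested samples/variants.
#' @export
subset_gm <- function(x, samples = NULL, variants = NULL, ...) {
  stopifnot(inherits(x, "genotype_matrix"))
  d <- x$dosages
  v <- x$variants
  if (!is.null(samples)) d <- d[samples, , drop = FALSE]
  if (!is.null(variants)) {
    if (is.character(variants)) variants <- match(variants, v$id)
    d <- d[, variants, drop = FALSE]
    v <- v[variants, , drop = FALSE]
    rownames(v) <- NULL
  }
  genotype_matrix(v, d)
}

#' Combine two genotype matrices over identical samples
#'
#' @param a,b genotype_matrix objects with identical sample sets (row order)
#' @return genotype_matrix with the variants of both, in order.
#' @export
cbind_gm <- function(a, b) {
  stopifnot(inherits(a, "genotype_matrix"), inherits(b, "genotype_matrix"))
  if (!identical(rownames(a$dosages), rownames(b$dosages)))
    stop("sample sets differ")
  genotype_matrix(rbind(a$variants, b$variants), cbind(a$dosages, b$dosages))
}

#' Population map constructor
#'
#' @param sample_id character vector of sample ids
#' @param population population label per sample
#' @param superpopulation superpopulation label per sample
#' @param admixed logical flag per sample marking membership in a recently
#'   admixed population (excluded when pooling outgroup frequencies)
#' @return data.frame of class `popmap`.
#' @export
population_map <- function(sample_id, population,
                           superpopulation = population,
                           admixed = FALSE) {
  if (anyDuplicated(sample_id)) stop("duplicated sample ids")
  pm <- data.frame(sample_id = as.character(sample_id),
                   population = as.character(population),
                   superpopulation = as.character(superpopulation),
                   admixed = rep_len(as.logical(admixed), length(sample_id)),
                   stringsAsFactors = FALSE)
  class(pm) <- c("popmap", "data.frame")
  pm
}

# split sample ids of a genotype matrix by population, in popmap order
pop_sample_index <- function(gm, popmap) {
  idx <- match(popmap$sample_id, rownames(gm$dosages))
  if (anyNA(idx))
    stop("popmap samples absent from genotype matrix: ",
         paste(utils::head(popmap$sample_id[is.na(idx)], 3), collapse = ", "))
  split(idx, factor(popmap$population, levels = unique(popmap$population)))
}
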