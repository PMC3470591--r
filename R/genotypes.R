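#' Construct a genotype matrix
#'
#' Wraps an n x p integer matrix of reference-allele counts (0, 1 or 2;
#' \code{NA} for missing) with sample and locus identifiers, validating the
#' coding.  Rows are individuals, columns are SNPs; loci are treated as
#' unordered exchangeable columns throughout the package (the allele-sharing
#' distance is locus-wise), so no genomic coordinates are kept.
#'
#' @param values numeric or integer matrix with entries in \{0, 1, 2\} or
#'   \code{NA}.
#' @param sample_ids character vector of unique row identifiers; defaults to
#'   existing rownames or \code{"sample_1"...}.
#' @param locus_ids character vector of column identifiers; defaults to
#'   existing colnames or \code{"snp_1"...}.
#' @return An integer matrix of class \code{"geno_matrix"} with dimnames set.
#' @examples
#' g <- geno_matrix(rbind(c(0, 1, 2), c(2, 1, 0)))
#' dim(g)
#' @export
geno_matrix <- function(values, sample_ids = NULL, locus_ids = NULL) {
  if (!is.matrix(values)) values <- as.matrix(values)
  n <- nrow(values)
  p <- ncol(values)
  if (n < 1L || p < 1L) stop("genotype matrix must have at least 1 row and 1 column")
  bad <- which(!is.na(values) & !(values %in% c(0, 1, 2)))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% n) + 1L
    j <- ((bad[1L] - 1L) %/% n) + 1L
    stop(sprintf("invalid genotype code '%s' at row %d, column %d (expected 0, 1, 2 or missing)",
                 format(values[bad[1L]]), i, j))
  }
  if (is.null(sample_ids)) sample_ids <- rownames(values)
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(n))
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  if (length(sample_ids) != n) stop("sample_ids length does not match row count")
  if (is.null(locus_ids)) locus_ids <- colnames(values)
  if (is.null(locus_ids)) locus_ids <- paste0("snp_", seq_len(p))
  if (length(locus_ids) != p) stop("locus_ids length does not match column count")
  storage.mode(values) <- "integer"
  dimnames(values) <- list(sample_ids, locus_ids)
  class(values) <- c("geno_matrix", class(values))
  values
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("genotype matrix: %d samples x %d SNPs (%.2f%% missing)\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

# tokens treated as missing genotypes in text input
.missing_tokens <- c("NA", "-9", ".")

#' Read a genotype matrix from a standard text format
#'
#' Supported formats:
#' \describe{
#'   \item{\code{matrix012}}{plain whitespace- or comma-separated table of
#'     0/1/2 codes; an optional header row of locus IDs and an optional first
#'     column of sample IDs are auto-detected (a non-numeric, non-missing
#'     first token marks them).}
#'   \item{\code{plink_raw}}{PLINK \code{--recode A} additive table; the
#'     header and the FID/IID/PAT/MAT/SEX/PHENOTYPE columns are recognised
#'     and skipped, IID becomes the sample ID.}
#'   \item{\code{vcf}}{minimal VCF 4.x via the vcfR package: biallelic SNPs
#'     only, GT field converted to the count of reference (REF) alleles,
#'     \code{./.} to missing.  Multi-allelic records are rejected.}
#' }
#' Missing genotypes may be written \code{NA}, \code{-9} or \code{.} in the
#' text formats and are stored uniformly as \code{NA}.
#'
#' @param path path to an existing file.
#' @param format one of \code{"matrix012"}, \code{"plink_raw"}, \code{"vcf"}.
#' @return A [geno_matrix()].
#' @export
read_genotype_matrix <- function(path, format = c("matrix012", "plink_raw", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  G <- switch(format,
              matrix012 = .read_matrix012(path),
              plink_raw = .read_plink_raw(path),
              vcf       = .read_vcf(path))
  if (nrow(G) < 2L)
    stop("genotype file holds fewer than 2 samples; clustering needs n >= 2")
  G
}

.is_code_token <- function(tok) tok %in% c("0", "1", "2") | tok %in% .missing_tokens

.read_matrix012 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty genotype file: ", path)
  split_line <- function(x) {
    toks <- strsplit(trimws(x), "[,[:space:]]+")[[1L]]
    toks[nzchar(toks)]
  }
  rows <- lapply(lines, split_line)
  # header present iff the first line holds non-code tokens beyond the first
  # position (a lone non-code first token is a sample ID, not a header)
  first <- rows[[1L]]
  has_header <- if (length(first) > 1L) !all(.is_code_token(first[-1L]))
                else !.is_code_token(first)
  locus_ids <- NULL
  if (has_header) {
    locus_ids <- first
    rows <- rows[-1L]
    if (!length(rows)) stop("genotype file has a header but no data rows: ", path)
  }
  first_toks <- vapply(rows, `[`, character(1L), 1L)
  has_ids <- !all(.is_code_token(first_toks))
  sample_ids <- NULL
  if (has_ids) {
    sample_ids <- first_toks
    rows <- lapply(rows, `[`, -1L)
  }
  widths <- lengths(rows)
  if (length(unique(widths)) != 1L)
    stop("ragged genotype matrix: rows have differing numbers of columns")
  p <- widths[1L]
  if (!is.null(locus_ids) && length(locus_ids) == p + 1L && has_ids)
    locus_ids <- locus_ids[-1L]  # header included a label for the ID column
  if (!is.null(locus_ids) && length(locus_ids) != p)
    stop("header length does not match number of genotype columns")
  toks <- matrix(unlist(rows, use.names = FALSE), nrow = length(rows), ncol = p, byrow = TRUE)
  bad <- which(!.is_code_token(toks))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(toks)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(toks)) + 1L
    stop(sprintf("invalid genotype token '%s' at data row %d, column %d of %s",
                 toks[bad[1L]], i, j, path))
  }
  toks[toks %in% .missing_tokens] <- NA
  vals <- matrix(as.integer(toks), nrow = nrow(toks), ncol = p)
  geno_matrix(vals, sample_ids = sample_ids, locus_ids = locus_ids)
}

.read_plink_raw <- function(path) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           na.strings = .missing_tokens, check.names = FALSE)
  meta <- intersect(c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"), names(tab))
  sample_ids <- if ("IID" %in% names(tab)) as.character(tab[["IID"]]) else NULL
  geno <- tab[, setdiff(names(tab), meta), drop = FALSE]
  if (!ncol(geno)) stop("no genotype columns found in PLINK raw file: ", path)
  vals <- as.matrix(geno)
  if (!is.numeric(vals)) stop("non-numeric genotype entries in PLINK raw file: ", path)
  geno_matrix(vals, sample_ids = sample_ids, locus_ids = colnames(geno))
}

.read_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  multi <- grepl(",", alt)
  if (any(multi))
    stop(sprintf("multi-allelic record(s) not supported (first at %s:%s)",
                 vcfR::getCHROM(v)[which(multi)[1L]], vcfR::getPOS(v)[which(multi)[1L]]))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt) || !ncol(gt)) stop("VCF contains no genotype (GT) data: ", path)
  # count of reference alleles in the GT string; './.' and '.' give NA
  count_ref <- function(g) {
    if (is.na(g)) return(NA_integer_)
    al <- strsplit(g, "[/|]")[[1L]]
    if (any(al == ".")) return(NA_integer_)
    if (length(al) != 2L) stop("non-diploid GT field: ", g)
    sum(al == "0")
  }
  vals <- t(apply(gt, 2L, function(col) vapply(col, count_ref, integer(1L))))
  if (nrow(gt) == 1L) vals <- matrix(as.integer(vals), ncol = 1L,
                                     dimnames = list(colnames(gt), NULL))
  locus_ids <- vcfR::getID(v)
  if (all(is.na(locus_ids))) locus_ids <- NULL
  geno_matrix(vals, sample_ids = colnames(gt), locus_ids = locus_ids)
}

#' Write and read a partition as TSV
#'
#' Two columns, \code{sample_id} and \code{cluster}; \code{read_partition}
#' inverts \code{write_partition} exactly.
#'
#' @param partition named integer vector mapping sample IDs to cluster labels
#'   (as produced by [prune_sequence()] or [ships_run()]).
#' @param path output file path.
#' @export
write_partition <- function(partition, path) {
  stopifnot(!is.null(names(partition)))
  utils::write.table(data.frame(sample_id = names(partition),
                                cluster = as.integer(partition)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  stats::setNames(as.integer(tab$cluster), as.character(tab$sample_id))
}

#' Write a gap table as TSV
#'
#' One row per realized cluster count with columns
#' \code{k, W, null_mean, null_sd, gap, s, selected}.
#'
#' @param gap a \code{ships_gap} object from [gap_curve()].
#' @param path output file path.
#' @export
write_gap_table <- function(gap, path) {
  tab <- as.data.frame(gap)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a cluster tree to Newick
#'
#' Leaves are written \code{cluster_<i>(n=<size>)} in left-to-right order;
#' branch lengths are omitted because divisive-split trees carry no branch
#' length information.
#'
#' @param tree a \code{ships_tree} from [build_tree()].
#' @param path output file path.
#' @export
write_tree <- function(tree, path) {
  counter <- new.env()
  counter$i <- 0L
  rec <- function(node) {
    if (is.null(node$children)) {
      counter$i <- counter$i + 1L
      sprintf("cluster_%d(n=%d)", counter$i, length(node$members))
    } else {
      paste0("(", paste(vapply(node$children, rec, character(1L)), collapse = ","), ")")
    }
  }
  txt <- rec(tree$root)
  if (is.null(tree$root$children)) txt <- paste0("(", txt, ")")
  writeLines(paste0(txt, ";"), path)
  invisible(path)
}
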