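#' Read biallelic SNP genotypes from a VCF file
#'
#' Parses a multi-sample VCF (v4.x, via \pkg{vcfR}) into a
#' [genotype_matrix()]. Only biallelic single-nucleotide records are kept:
#' multi-allelic records and indels are skipped and counted. Genotypes are
#' decoded from the GT field as ALT-allele dosages; phased (`0|1`) and
#' unphased (`0/1`) calls are treated identically, and any call that is not
#' fully diploid-called (`./.`, `.`, half-calls such as `./1`) becomes
#' missing, because a dosage is undefined for it.
#'
#' @param path Path to a VCF file (plain text or gzipped).
#' @param keep_monomorphic Keep loci with no observed ALT (or no REF)
#'   allele? Default `TRUE`; downstream MAF filtering normally removes them.
#' @return A `genotype_matrix`. The number of skipped non-biallelic-SNP
#'   records is attached as attribute `"n_skipped"`.
#' @seealso [write_vcf()] for the minimal fixture writer.
#' @export
read_vcf <- function(path, keep_monomorphic = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (!length(first) || !startsWith(first, "##fileformat=VCF")) {
    stop("not a VCF file (missing ##fileformat header line): ", path)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (ncol(v@gt) < 2L) stop("VCF contains no sample columns")
  fix <- v@fix
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snp <- !is.na(alt) & !grepl(",", alt, fixed = TRUE) &
    nchar(ref) == 1L & nchar(alt) == 1L & ref != alt
  n_skipped <- sum(!snp)
  if (n_skipped > 0L) {
    message(n_skipped, " record(s) skipped (multi-allelic or not a SNP)")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[snp, , drop = FALSE]
  fix <- fix[snp, , drop = FALSE]
  calls <- t(decode_gt(gt))
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], "_", fix[, "POS"])[is.na(ids) | ids == "."]
  loci <- data.frame(
    id = make.unique(ids), chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]), ref = fix[, "REF"], alt = fix[, "ALT"],
    qual = suppressWarnings(as.numeric(fix[, "QUAL"])),
    stringsAsFactors = FALSE
  )
  gm <- genotype_matrix(calls, loci, samples = colnames(v@gt)[-1L])
  if (!keep_monomorphic && n_loci(gm) > 0L) {
    mono <- vapply(seq_len(n_loci(gm)), function(k) {
      x <- gm$calls[, k]
      x <- x[!is.na(x)]
      length(x) == 0L || sum(x) == 0L || sum(x) == 2L * length(x)
    }, logical(1))
    gm <- subset_loci(gm, !mono)
  }
  attr(gm, "n_skipped") <- n_skipped
  gm
}

# GT strings -> dosage codes; anything not fully called becomes NA.
decode_gt <- function(gt) {
  lut <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  out <- lut[chartr("|", "/", gt)]
  dim(out) <- dim(gt)
  dimnames(out) <- dimnames(gt)
  out
}

#' Write a genotype matrix as a minimal VCF
#'
#' Deterministic plain-text VCF v4.2 writer used to materialize simulated
#' fixtures so the full pipeline can be driven through files. Only the
#' fields the package itself reads are written (CHROM, POS, ID, REF, ALT,
#' QUAL and per-sample GT); identical inputs give byte-identical files.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  g <- c("0/0", "0/1", "1/1")[gm$calls + 1L]
  g[is.na(g)] <- "./."
  dim(g) <- dim(gm$calls)
  qual <- ifelse(is.na(gm$loci$qual), ".", formatC(gm$loci$qual, format = "g", digits = 15))
  body <- paste(gm$loci$chrom, gm$loci$pos, gm$loci$id, gm$loci$ref, gm$loci$alt,
                qual, ".", ".", "GT",
                apply(g, 2L, paste, collapse = "\t"), sep = "\t")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=snpkin",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t")
  )
  writeLines(c(header, if (n_loci(gm) > 0L) body), path)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Reads the per-individual metadata used throughout the package: sample
#' id, population label (the sampling location) and position along the
#' river in km upstream of a fixed origin. Tab- and comma-separated files
#' are both accepted; the separator is sniffed from the header line.
#'
#' @param path Path to a delimited text file with header columns
#'   `sample_id`, `population`, `river_km`.
#' @return A data frame with those three columns (`river_km` numeric).
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, check.names = TRUE)
  for (col in c("sample_id", "population", "river_km")) {
    if (!col %in% names(tab)) stop("missing required column: ", col)
  }
  tab <- tab[, c("sample_id", "population", "river_km")]
  tab$sample_id <- as.character(tab$sample_id)
  tab$population <- as.character(tab$population)
  if (anyDuplicated(tab$sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(tab$sample_id[duplicated(tab$sample_id)]), collapse = ", "))
  }
  if (any(!nzchar(tab$population))) stop("empty population label")
  tab$river_km <- as.numeric(tab$river_km)
  if (any(is.na(tab$river_km)) || any(tab$river_km < 0)) {
    stop("river_km must be non-negative numbers")
  }
  tab
}

#' Write and read square labelled matrices
#'
#' Relationship and distance matrices are exchanged as TSV with the ids as
#' both header row and first column. Values are written with enough digits
#' that a write/read round trip reproduces them to better than 1e-12.
#'
#' @param m Numeric square matrix, symmetric to within 1e-10.
#' @param ids Character vector of row/column ids (defaults to rownames).
#' @param path Output (or input) file path.
#' @return `write_square_matrix()` returns `path` invisibly;
#'   `read_square_matrix()` returns the labelled matrix.
#' @export
write_square_matrix <- function(m, ids = rownames(m), path) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("`m` must be a square matrix")
  if (is.null(ids)) stop("row/column ids are required")
  if (length(ids) != nrow(m)) stop("id count (", length(ids),
                                   ") does not match matrix order (", nrow(m), ")")
  if (max(abs(m - t(m))) > 1e-10) stop("matrix is not symmetric (tolerance 1e-10)")
  lines <- c(paste(c("id", ids), collapse = "\t"),
             paste(ids, apply(m, 1L, function(r) {
               paste(formatC(r, format = "g", digits = 17), collapse = "\t")
             }), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_square_matrix
#' @export
read_square_matrix <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                           row.names = 1L, stringsAsFactors = FALSE)
  m <- as.matrix(tab)
  if (nrow(m) != ncol(m)) stop("file does not contain a square matrix")
  m
}

#' Write a pair table as TSV
#'
#' @param pairs Data frame as returned by [pair_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pair_table <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
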