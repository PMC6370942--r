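## Readers and writers for the genotype formats the pipeline touches:
## VCF v4.2 (GT and GP FORMAT fields, INFO/R2/DR2 quality keys) and the
## Oxford GEN/SAMPLE pair. Probabilities are linear-scale throughout, as
## emitted by Minimac and PBWT. B allele = ALT / alleleB column.

QUALITY_KEYS <- c("INFO", "R2", "DR2")

normalise_chrom <- function(chrom) {
  chrom <- sub("^chr", "", as.character(chrom))
  chrom[chrom == "23"] <- "X"
  chrom
}

#' Read a VCF file into a genotype container
#'
#' Parses a (possibly gzip-compressed) VCF v4.2 file. With `require_gp =
#' TRUE` every record must carry a three-value linear-scale `GP` FORMAT field
#' and the result is a [prob_genotype_matrix()] whose per-variant quality is
#' taken from the first INFO key found among `INFO`, `R2`, `DR2` (missing ->
#' `NA`). Otherwise hard `GT` genotypes are read into a [genotype_matrix()],
#' with `./.` mapped to a missing call. Multiallelic and symbolic-allele
#' records, and records on chromosomes outside 1-22/X, are skipped; the
#' count of skipped records is reported via `message()` and attached as
#' attribute `"n_skipped"`. Sample and variant order follow the file.
#'
#' @param path path to a VCF file (`.vcf` or `.vcf.gz`).
#' @param require_gp logical; demand genotype probabilities (default FALSE).
#' @return A `prob_genotype_matrix` (with `require_gp = TRUE`) or a
#'   `genotype_matrix`.
#' @export
read_vcf <- function(path, require_gp = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  n_header <- length(v@meta) + 1L  # meta lines + the #CHROM header line
  fix <- v@fix
  if (nrow(fix) == 0L) stop("VCF contains no records: ", path)
  line_no <- n_header + seq_len(nrow(fix))

  chrom <- normalise_chrom(fix[, "CHROM"])
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  skip <- is.na(alt) | grepl(",", alt, fixed = TRUE) |
    grepl("[<>*]", alt) | grepl("[<>*]", ref) |
    !chrom %in% VALID_CHROMS
  n_skipped <- sum(skip)
  if (n_skipped > 0L) {
    message("read_vcf: skipped ", n_skipped,
            " multiallelic/symbolic/off-target record(s)")
  }
  keep <- which(!skip)
  if (length(keep) == 0L) stop("no usable biallelic records in ", path)

  pos <- suppressWarnings(as.integer(fix[keep, "POS"]))
  bad <- is.na(pos) | !grepl("^[ACGTacgt]+$", ref[keep]) |
    !grepl("^[ACGTacgt]+$", alt[keep])
  if (any(bad)) {
    stop("malformed VCF record at line ", line_no[keep][which(bad)[1L]])
  }
  ids <- fix[keep, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(chrom[keep], ":", pos)[is.na(ids) | ids == "."]
  vt <- variant_table(chrom[keep], pos, ids,
                      toupper(ref[keep]), toupper(alt[keep]))
  samples <- colnames(v@gt)[-1L]

  if (require_gp) {
    fmt <- v@gt[keep, 1L]
    if (!all(grepl("(^|:)GP(:|$)", fmt))) {
      stop("require_gp: no GP genotype-probability field in ", path)
    }
    gp <- vcfR::extract.gt(v, element = "GP")[keep, , drop = FALSE]
    probs <- parse_gp_strings(gp, line_no[keep])
    quality <- parse_info_quality(fix[keep, "INFO"])
    out <- prob_genotype_matrix(probs, vt, samples, quality)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
    calls <- parse_gt_strings(gt, line_no[keep])
    out <- genotype_matrix(t(calls), vt, samples)
  }
  attr(out, "n_skipped") <- n_skipped
  out
}

## variants x samples character matrix of "p0,p1,p2" -> samples x variants x 3
parse_gp_strings <- function(gp, line_no) {
  nv <- nrow(gp); ns <- ncol(gp)
  gp_vec <- as.vector(gp)                       # column-major: variant fastest
  miss <- is.na(gp_vec) | gp_vec == "."
  gp_vec[miss] <- "0,0,0"                       # per-sample no-call sentinel
  parts <- strsplit(gp_vec, ",", fixed = TRUE)
  lens <- lengths(parts)
  if (any(lens != 3L)) {
    bad_var <- ((which(lens != 3L)[1L] - 1L) %% nv) + 1L
    stop("GP field is not a 3-value triple at line ", line_no[bad_var])
  }
  num <- suppressWarnings(as.numeric(unlist(parts, use.names = FALSE)))
  if (anyNA(num)) {
    bad_var <- (((which(is.na(num))[1L] - 1L) %/% 3L) %% nv) + 1L
    stop("non-numeric GP value at line ", line_no[bad_var])
  }
  # num is grouped in triples, variant-fastest within each sample column
  arr <- array(num, dim = c(3L, nv, ns))
  aperm(arr, c(3L, 2L, 1L))
}

## variants x samples character matrix of GT strings -> variants x samples int
parse_gt_strings <- function(gt, line_no) {
  map <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L, "0|1" = 1L,
           "1|0" = 1L, "1/1" = 2L, "1|1" = 2L, "0" = 0L, "1" = 2L)
  gt_vec <- as.vector(gt)
  out <- map[gt_vec]
  unknown <- is.na(out) & !is.na(gt_vec) & gt_vec != "./." & gt_vec != ".|." &
    gt_vec != "." & !grepl("\\.", gt_vec)
  if (any(unknown)) {
    bad_var <- ((which(unknown)[1L] - 1L) %% nrow(gt)) + 1L
    stop("unparseable GT '", gt_vec[which(unknown)[1L]], "' at line ",
         line_no[bad_var])
  }
  matrix(unname(out), nrow = nrow(gt), ncol = ncol(gt))
}

## INFO column strings -> per-variant quality (key precedence INFO > R2 > DR2)
parse_info_quality <- function(info) {
  out <- rep(NA_real_, length(info))
  for (key in QUALITY_KEYS) {
    pat <- paste0("(?:^|;)", key, "=([^;]+)")
    m <- regmatches(info, regexec(pat, info, perl = TRUE))
    val <- vapply(m, function(x) if (length(x) == 2L) x[2L] else NA_character_,
                  character(1))
    fill <- is.na(out) & !is.na(val)
    out[fill] <- suppressWarnings(as.numeric(val[fill]))
  }
  pmin(pmax(out, 0), 1)
}

vcf_header_lines <- function(samples, with_gp) {
  fmt <- c('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  info <- character(0)
  if (with_gp) {
    fmt <- c(fmt, paste0('##FORMAT=<ID=GP,Number=G,Type=Float,',
                         'Description="Genotype posterior probabilities">'))
    info <- paste0('##INFO=<ID=R2,Number=1,Type=Float,',
                   'Description="Imputation quality">')
  }
  c("##fileformat=VCFv4.2", info, fmt,
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

#' Write a genotype container as VCF
#'
#' `genotype_matrix` objects are written with a `GT`-only FORMAT (missing
#' calls as `./.`); `prob_genotype_matrix` objects are written as `GT:GP`
#' with the per-variant quality score in the INFO column as `R2=` (or `.`
#' when undefined). A matrix written and re-read round-trips exactly.
#'
#' @param x a `genotype_matrix` or `prob_genotype_matrix`.
#' @param path output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) UseMethod("write_vcf")

#' @export
write_vcf.genotype_matrix <- function(x, path) {
  codes <- c("0/0", "0/1", "1/1")
  gt <- matrix(codes[x$calls + 1L], nrow = nrow(x$calls))
  gt[is.na(x$calls)] <- "./."
  body <- paste(x$variants$chrom, x$variants$pos, x$variants$id,
                x$variants$a1, x$variants$a2, ".", ".", ".", "GT",
                apply(gt, 2L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(vcf_header_lines(x$samples, FALSE), body), path)
  invisible(path)
}

#' @export
write_vcf.prob_genotype_matrix <- function(x, path) {
  ns <- length(x$samples); nv <- nrow(x$variants)
  gt <- hard_call_codes(x)
  fmt3 <- function(p) formatC(p, format = "g", digits = 6)
  cell <- matrix(paste0(gt, ":",
                        fmt3(as.vector(x$probs[, , 1L])), ",",
                        fmt3(as.vector(x$probs[, , 2L])), ",",
                        fmt3(as.vector(x$probs[, , 3L]))),
                 nrow = ns, ncol = nv)
  info <- ifelse(is.na(x$quality), ".",
                 paste0("R2=", formatC(x$quality, format = "g", digits = 6)))
  body <- paste(x$variants$chrom, x$variants$pos, x$variants$id,
                x$variants$a1, x$variants$a2, ".", ".", info, "GT:GP",
                apply(cell, 2L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(vcf_header_lines(x$samples, TRUE), body), path)
  invisible(path)
}

## GT codes from the probability argmax (unique max, no threshold); used only
## for the cosmetic GT field accompanying GP output
hard_call_codes <- function(pgm) {
  p0 <- pgm$probs[, , 1L]; p1 <- pgm$probs[, , 2L]; p2 <- pgm$probs[, , 3L]
  m <- pmax(p0, p1, p2)
  ties <- (p0 == m) + (p1 == m) + (p2 == m)
  code <- ifelse(ties > 1L | m == 0, "./.",
                 ifelse(p2 == m, "1/1", ifelse(p1 == m, "0/1", "0/0")))
  matrix(code, nrow = dim(pgm$probs)[1L])
}

#' Read an Oxford GEN/SAMPLE file pair
#'
#' The GEN file is space-delimited with five leading columns (chromosome,
#' variant id, position, alleleA, alleleB) followed by one probability triple
#' (AA, AB, BB) per sample, B being the alleleB column. The SAMPLE file has
#' two header lines; sample IDs are taken from its second column. An all-zero
#' triple is kept as `(0, 0, 0)` and becomes a no-call at calling time.
#'
#' @param gen_path path to the GEN file.
#' @param sample_path path to the SAMPLE file.
#' @return A [prob_genotype_matrix()] (quality undefined: GEN carries none).
#' @export
read_gen_sample <- function(gen_path, sample_path) {
  smp <- utils::read.table(sample_path, header = FALSE, skip = 2L,
                           stringsAsFactors = FALSE)
  samples <- as.character(smp[[min(2L, ncol(smp))]])
  ns <- length(samples)

  lines <- readLines(gen_path)
  if (length(lines) == 0L) stop("empty GEN file: ", gen_path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  expected <- 5L + 3L * ns
  widths <- lengths(fields)
  if (any(widths != expected)) {
    bad <- which(widths != expected)[1L]
    stop("GEN line ", bad, " has ", widths[bad], " fields; expected ",
         expected, " for ", ns, " sample(s)")
  }
  mat <- matrix(unlist(fields, use.names = FALSE), ncol = expected,
                byrow = TRUE)
  nv <- nrow(mat)
  probs_num <- suppressWarnings(as.numeric(mat[, -(1:5), drop = FALSE]))
  if (anyNA(probs_num)) stop("non-numeric probability value in ", gen_path)
  if (min(probs_num) < 0) {
    stop("negative genotype probability in ", gen_path)
  }
  pm <- matrix(probs_num, nrow = nv)           # nv x (3*ns)
  probs <- array(0, dim = c(ns, nv, 3L))
  # columns for sample s are (3(s-1)+1):(3(s-1)+3) of pm
  for (k in 1:3) {
    probs[, , k] <- t(pm[, 3L * (seq_len(ns) - 1L) + k, drop = FALSE])
  }
  vt <- variant_table(normalise_chrom(mat[, 1L]),
                      suppressWarnings(as.integer(mat[, 3L])),
                      mat[, 2L], mat[, 4L], mat[, 5L])
  prob_genotype_matrix(probs, vt, samples)
}

#' Write an Oxford GEN/SAMPLE file pair
#'
#' Inverse of [read_gen_sample()]; probabilities are printed with the same
#' precision as [write_vcf()] so that the two serialisations of one dataset
#' parse back to identical probability triples.
#'
#' @param pgm a `prob_genotype_matrix`.
#' @param gen_path,sample_path output paths.
#' @return `gen_path`, invisibly.
#' @export
write_gen_sample <- function(pgm, gen_path, sample_path) {
  ns <- length(pgm$samples); nv <- nrow(pgm$variants)
  fmt3 <- function(p) formatC(p, format = "g", digits = 6)
  tri <- matrix("", nrow = ns, ncol = nv)
  tri[] <- paste(fmt3(as.vector(pgm$probs[, , 1L])),
                 fmt3(as.vector(pgm$probs[, , 2L])),
                 fmt3(as.vector(pgm$probs[, , 3L])))
  body <- paste(pgm$variants$chrom, pgm$variants$id, pgm$variants$pos,
                pgm$variants$a1, pgm$variants$a2,
                apply(tri, 2L, paste, collapse = " "))
  writeLines(body, gen_path)
  writeLines(c("ID_1 ID_2 missing", "0 0 0",
               paste(pgm$samples, pgm$samples, "0")), sample_path)
  invisible(gen_path)
}
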