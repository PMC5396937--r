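#' SNP genotype matrices
#'
#' `genotype_matrix()` builds the package's container for biallelic SNP
#' calls: an integer matrix of individuals x loci with values 0 (homozygous
#' for the locus's first allele), 1 (heterozygous), 2 (homozygous for the
#' second allele) and `NA` (missing), plus per-locus allele pairs and
#' per-sample population/generation labels.
#'
#' @param calls integer matrix, individuals in rows, loci in columns;
#'   values in {0, 1, 2, NA}.
#' @param alleles data frame with columns `locus`, `a1`, `a2` (single
#'   nucleotide states; `a2` may be `NA` for a locus seen only monomorphic).
#' @param samples data frame with columns `id` and optionally `population`,
#'   `generation`.
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, alleles, samples) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  stopifnot(all(calls %in% c(0L, 1L, 2L, NA)),
            nrow(alleles) == ncol(calls), nrow(samples) == nrow(calls))
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  samples$id <- as.character(samples$id)
  if (anyDuplicated(samples$id)) stop("duplicate sample ids")
  alleles <- as.data.frame(alleles, stringsAsFactors = FALSE)
  if (anyDuplicated(alleles$locus)) stop("duplicate locus ids")
  if (is.null(samples$population)) samples$population <- "pop1"
  if (is.null(samples$generation)) samples$generation <- NA_integer_
  dimnames(calls) <- list(samples$id, alleles$locus)
  structure(list(calls = calls, alleles = alleles, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "genotype_matrix: %d individuals x %d loci (%.1f%% missing)\n",
    nrow(x$calls), ncol(x$calls), 100 * mean(is.na(x$calls))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

# IUPAC single-letter genotype dialect: a base letter is the homozygote for
# that base, a two-base ambiguity code is the heterozygote, N is missing.
.iupac_het <- c(M = "AC", R = "AG", W = "AT", S = "CG", Y = "CT", K = "GT")
.iupac_hom <- c("A", "C", "G", "T")

iupac_code_for <- function(a1, a2) {
  if (is.na(a2)) return(NULL)
  names(.iupac_het)[match(paste0(pmin(a1, a2), pmax(a1, a2)), .iupac_het)]
}

#' Read a genotype matrix
#'
#' Supports two plain-text dialects: `"iupac"` (tab-delimited, genotypes as
#' IUPAC single-letter codes, `N` = missing) and `"numeric"` (0/1/2 dosage
#' codes, `NA` or empty = missing). Individuals are rows by default;
#' the export orientation of archived tables varies, so
#' `orientation = "loci"` reads a transposed table (loci as rows).
#' Allele pairs are inferred per locus from the observed codes; a locus
#' implying more than two alleles is a data error.
#'
#' Recognized non-locus columns (by header name): `sample` (or `id`),
#' `population`, `generation`.
#'
#' @param path file path.
#' @param dialect `"iupac"` or `"numeric"`.
#' @param orientation `"individuals"` (default) or `"loci"` for rows.
#' @return a [genotype_matrix()].
#' @export
read_genotype_matrix <- function(path, dialect = c("iupac", "numeric"),
                                 orientation = c("individuals", "loci")) {
  dialect <- match.arg(dialect)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("genotype file not found: ", path)
  raw <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                      colClasses = "character"),
    error = function(e) stop("cannot parse genotype table (",
                             conditionMessage(e), "): ", path))
  if (nrow(raw) == 0L || ncol(raw) < 2L)
    stop("cannot parse genotype table (empty or single column): ", path)
  meta_cols <- intersect(c("sample", "id", "population", "generation"),
                         names(raw))
  if (orientation == "loci") {
    locus_ids <- raw[[1]]
    mat <- t(as.matrix(raw[, -1, drop = FALSE]))
    colnames(mat) <- locus_ids
    samples <- data.frame(id = rownames(mat), stringsAsFactors = FALSE)
  } else {
    idc <- intersect(c("sample", "id"), names(raw))[1]
    if (is.na(idc)) stop("no 'sample' or 'id' column in genotype table")
    samples <- data.frame(id = raw[[idc]], stringsAsFactors = FALSE)
    if ("population" %in% meta_cols) samples$population <- raw$population
    if ("generation" %in% meta_cols)
      samples$generation <- as.integer(raw$generation)
    mat <- as.matrix(raw[, setdiff(names(raw), meta_cols), drop = FALSE])
    rownames(mat) <- samples$id
  }
  if (ncol(mat) == 0L) stop("genotype table has no locus columns: ", path)
  if (dialect == "numeric") {
    calls <- suppressWarnings(matrix(as.integer(mat), nrow(mat), ncol(mat),
                                     dimnames = dimnames(mat)))
    bad <- !is.na(mat) & mat != "" & mat != "NA" & is.na(calls)
    bad <- bad | (!is.na(calls) & !(calls %in% 0:2))
    if (any(bad)) {
      w <- which(bad, arr.ind = TRUE)[1, ]
      stop("unknown numeric genotype code '", mat[w[1], w[2]],
           "' at row ", w[1], ", locus ", colnames(mat)[w[2]])
    }
    alleles <- data.frame(locus = colnames(mat), a1 = NA_character_,
                          a2 = NA_character_, stringsAsFactors = FALSE)
    return(genotype_matrix(calls, alleles, samples))
  }
  mat[mat == ""] <- "N"
  known <- c(.iupac_hom, names(.iupac_het), "N")
  bad <- !(mat %in% known)
  dim(bad) <- dim(mat)   # %in% drops dimensions
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop("unknown IUPAC genotype code '", mat[w[1], w[2]],
         "' at row ", w[1], ", locus ", colnames(mat)[w[2]])
  }
  calls <- matrix(NA_integer_, nrow(mat), ncol(mat), dimnames = dimnames(mat))
  a1 <- a2 <- rep(NA_character_, ncol(mat))
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    obs <- setdiff(unique(col), "N")
    letters_seen <- sort(unique(unlist(strsplit(
      ifelse(obs %in% names(.iupac_het), .iupac_het[obs], obs), ""))))
    if (length(letters_seen) > 2L)
      stop("locus ", colnames(mat)[j], " implies more than two alleles: ",
           paste(letters_seen, collapse = "/"))
    if (length(letters_seen) >= 1L) a1[j] <- letters_seen[1]
    if (length(letters_seen) == 2L) a2[j] <- letters_seen[2]
    calls[col == a1[j], j] <- 0L
    if (!is.na(a2[j])) {
      calls[col == a2[j], j] <- 2L
      calls[col == names(.iupac_het)[match(paste0(a1[j], a2[j]), .iupac_het)],
            j] <- 1L
    }
  }
  alleles <- data.frame(locus = colnames(mat), a1 = a1, a2 = a2,
                        stringsAsFactors = FALSE)
  genotype_matrix(calls, alleles, samples)
}

#' Write a genotype matrix
#'
#' Inverse of [read_genotype_matrix()]; the IUPAC dialect needs known
#' allele pairs (as produced by the simulator or inferred on read).
#'
#' @param gm a [genotype_matrix()].
#' @inheritParams read_genotype_matrix
#' @return `path`, invisibly.
#' @export
write_genotype_matrix <- function(gm, path, dialect = c("iupac", "numeric")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(gm, "genotype_matrix"))
  n <- nrow(gm$calls)
  if (dialect == "numeric") {
    out <- as.data.frame(gm$calls)
  } else {
    out <- as.data.frame(matrix("N", n, ncol(gm$calls)),
                         stringsAsFactors = FALSE)
    names(out) <- gm$alleles$locus
    for (j in seq_len(ncol(gm$calls))) {
      a1 <- gm$alleles$a1[j]; a2 <- gm$alleles$a2[j]
      if (is.na(a1)) stop("cannot write IUPAC dialect: locus ",
                          gm$alleles$locus[j], " has unknown alleles")
      g <- gm$calls[, j]
      out[[j]][!is.na(g) & g == 0L] <- a1
      if (!is.na(a2)) {
        out[[j]][!is.na(g) & g == 2L] <- a2
        out[[j]][!is.na(g) & g == 1L] <- iupac_code_for(a1, a2)
      } else if (any(!is.na(g) & g > 0L)) {
        stop("locus ", gm$alleles$locus[j],
             " has het/alt calls but only one known allele")
      }
    }
  }
  meta <- data.frame(sample = gm$samples$id, stringsAsFactors = FALSE)
  if (!all(gm$samples$population == "pop1"))
    meta$population <- gm$samples$population
  if (!all(is.na(gm$samples$generation)))
    meta$generation <- gm$samples$generation
  utils::write.table(cbind(meta, out), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Import biallelic SNP genotypes from a VCF file
#'
#' GT-field import via `VariantAnnotation::readVcf()`: keeps biallelic SNP
#' records only, maps `0/0`, `0|0` to 0, `0/1` to 1, `1/1` to 2, and
#' `./.` to missing. Multiallelic or indel records are dropped with a
#' message.
#'
#' @param path path to a VCF file.
#' @return a [genotype_matrix()].
#' @export
read_vcf_genotypes <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("read_vcf_genotypes() needs the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  altl <- rr$ALT
  keep <- which(lengths(altl) == 1L &
                  nchar(ref) == 1L &
                  vapply(altl, function(a) {
                    a <- as.character(a)
                    length(a) == 1L && a %in% c("A", "C", "G", "T")
                  }, logical(1)) &
                  ref %in% c("A", "C", "G", "T"))
  if (length(keep) < length(rr))
    message("dropping ", length(rr) - length(keep),
            " non-biallelic-SNP VCF records")
  if (!length(keep)) stop("no biallelic SNP records in VCF: ", path)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("no GT field in VCF: ", path)
  gt <- gt[keep, , drop = FALSE]
  locus <- rownames(gt)
  a1 <- ref[keep]
  a2 <- vapply(altl[keep], function(a) as.character(a)[1], character(1))
  sample_ids <- colnames(gt)
  code <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
            "0|0" = 0L, "0|1" = 1L, "1|0" = 1L, "1|1" = 2L)
  calls <- t(matrix(code[gt], nrow = nrow(gt), ncol = ncol(gt)))
  dimnames(calls) <- list(sample_ids, locus)
  # order allele pair alphabetically for consistency with the IUPAC reader
  flip <- !is.na(a2) & a2 < a1
  if (any(flip)) {
    calls[, flip] <- 2L - calls[, flip]
    tmp <- a1[flip]; a1[flip] <- a2[flip]; a2[flip] <- tmp
  }
  genotype_matrix(calls,
                  data.frame(locus = locus, a1 = a1, a2 = a2,
                             stringsAsFactors = FALSE),
                  data.frame(id = sample_ids, stringsAsFactors = FALSE))
}

#' Minor-allele definition and frequencies
#'
#' The minor allele at each locus is fixed once, from a reference set of
#' genotypes (by design the generation-1 founder-offspring cohort), and the
#' same allele is tracked through every later generation so that
#' frequencies remain comparable. Ties at 0.5 break toward the locus's
#' alphabetically first allele.
#'
#' @param gm a [genotype_matrix()].
#' @param reference logical or index vector choosing the rows that define
#'   the minor allele (default: all rows).
#' @return `minor_allele()`: integer vector (1 = locus allele `a1` is minor,
#'   2 = allele `a2`). `minor_freq()`: numeric vector of minor-allele
#'   frequencies among non-missing calls in the selected rows.
#' @export
minor_allele <- function(gm, reference = NULL) {
  calls <- gm$calls
  if (!is.null(reference)) calls <- calls[reference, , drop = FALSE]
  q2 <- colMeans(calls, na.rm = TRUE) / 2   # frequency of allele a2
  # ties (0.5) break toward a1, which is the alphabetically first allele
  ifelse(is.nan(q2) | q2 < 0.5, 2L, 1L)
}

#' @rdname minor_allele
#' @param minor integer vector from `minor_allele()` (recomputed if omitted).
#' @param rows subset of rows over which to compute frequencies.
#' @export
minor_freq <- function(gm, minor = NULL, rows = NULL) {
  if (is.null(minor)) minor <- minor_allele(gm)
  calls <- gm$calls
  if (!is.null(rows)) calls <- calls[rows, , drop = FALSE]
  q2 <- colMeans(calls, na.rm = TRUE) / 2
  ifelse(minor == 2L, q2, 1 - q2)
}
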