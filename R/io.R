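# Real-data entry points: VCF (GT or DS) and plain dosage TSV.

#' Read genotypes from a VCF or dosage TSV into a GenotypePanel
#'
#' Dosages are oriented to the minor allele (columns with coded-allele
#' frequency above 0.5 are flipped to `2 - dosage`), variants below the maf
#' floor are dropped with a message reporting the count, and sporadic
#' missing genotypes are mean-imputed with a warning. Variants missing in
#' more than `maxMissing` of samples, or with non-diploid GT fields, raise
#' an error.
#'
#' @param path path to the input file.
#' @param format `"vcf"` (GT or DS FORMAT fields, DS preferred when present)
#'   or `"dosage_tsv"` (variants x samples; first column `variant_id`,
#'   remaining columns one per sample).
#' @param metadata optional path to a metadata TSV with columns
#'   `id`, `position` (and optionally `maf`, ignored in favour of empirical
#'   frequencies) for `"dosage_tsv"` input; if absent, positions default to
#'   the variant order.
#' @param mafFloor minimum minor allele frequency retained (default 0.01,
#'   the common-variant universe).
#' @param maxMissing maximum tolerated per-variant missingness fraction.
#' @return A [GenotypePanel-class].
#' @seealso [writeDosageTsv()]
#' @export
readGenotypes <- function(path, format = c("vcf", "dosage_tsv"),
                          metadata = NULL, mafFloor = 0.01,
                          maxMissing = 0.1) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "vcf") {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fmt <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
    if (all(is.na(fmt))) {
      gt <- vcfR::extract.gt(vcf, element = "GT")
      fmt <- .gtToDosage(gt)
    }
    dos <- t(fmt)                                   # samples x variants
    ids <- colnames(dos)
    if (is.null(ids)) ids <- paste0("var", seq_len(ncol(dos)))
    pos <- as.numeric(vcfR::getPOS(vcf))
  } else {
    tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(tab[[1L]])
    dos <- t(as.matrix(tab[, -1L, drop = FALSE]))
    colnames(dos) <- ids
    pos <- seq_along(ids)
    if (!is.null(metadata)) {
      md <- read.delim(metadata, stringsAsFactors = FALSE)
      stopifnot(all(c("id", "position") %in% names(md)))
      pos <- md$position[match(ids, md$id)]
      if (anyNA(pos)) stop("metadata is missing positions for some variants",
                           call. = FALSE)
    }
  }
  .panelFromDosages(dos, pos, ids, mafFloor = mafFloor,
                    maxMissing = maxMissing)
}

# GT strings -> dosage matrix (variants x samples); errors on mixed ploidy
.gtToDosage <- function(gt) {
  u <- unique(as.vector(gt))
  u <- u[!is.na(u)]
  bad <- !grepl("^[0-9]+([/|][0-9]+)?$", u)
  if (any(bad)) stop("unparseable GT value(s): ",
                     paste(u[bad], collapse = ", "), call. = FALSE)
  if (any(!grepl("[/|]", u)))
    stop("haploid GT calls found; mixed or non-diploid ploidy is not supported",
         call. = FALSE)
  apply(gt, c(1L, 2L), function(x) {
    if (is.na(x)) return(NA_real_)
    sum(as.numeric(strsplit(x, "[/|]")[[1L]]) > 0)
  })
}

.panelFromDosages <- function(dos, pos, ids, mafFloor, maxMissing) {
  storage.mode(dos) <- "double"
  missFrac <- colMeans(is.na(dos))
  if (any(missFrac > maxMissing))
    stop(sum(missFrac > maxMissing), " variant(s) exceed the missingness ",
         "threshold of ", maxMissing, call. = FALSE)
  if (any(missFrac > 0)) {
    warning("mean-imputing sporadic missing genotypes in ",
            sum(missFrac > 0), " variant(s)", call. = FALSE)
    for (j in which(missFrac > 0)) {
      dos[is.na(dos[, j]), j] <- mean(dos[, j], na.rm = TRUE)
    }
  }
  # orient to the minor allele
  freq <- colMeans(dos) / 2
  flip <- freq > 0.5
  if (any(flip)) dos[, flip] <- 2 - dos[, flip, drop = FALSE]
  maf <- pmin(freq, 1 - freq)
  keep <- maf >= mafFloor & maf > 0
  if (any(!keep))
    message("dropped ", sum(!keep), " variant(s) below maf floor ", mafFloor)
  if (!any(keep)) stop("no variants remain after maf filtering", call. = FALSE)
  # resolve position ties so panel coordinates stay strictly increasing
  pos <- pos[keep]
  ord <- order(pos)
  pos <- pos[ord] + seq_along(pos) * 0  # keep numeric
  dup <- duplicated(pos)
  if (any(dup)) pos <- pos + cumsum(dup) * 1e-3
  GenotypePanel(dos[, keep, drop = FALSE][, ord, drop = FALSE],
                positions = pos, variantIds = ids[keep][ord],
                sampleIds = rownames(dos))
}

#' Write a GenotypePanel as a dosage TSV (plus metadata TSV)
#'
#' The dosage table is variants x samples with a `variant_id` first column;
#' the companion metadata file carries `id`, `position` and `maf`. The pair
#' round-trips through [readGenotypes()] with `format = "dosage_tsv"`.
#'
#' @param G a [GenotypePanel-class].
#' @param path output TSV path.
#' @param metadataPath optional metadata TSV path (default: `path` with a
#'   `.meta.tsv` suffix).
#' @return Invisibly, the two file paths.
#' @export
writeDosageTsv <- function(G, path, metadataPath = NULL) {
  if (is.null(metadataPath))
    metadataPath <- sub("\\.tsv$", "", path)
  if (identical(metadataPath, path) || !grepl("\\.meta\\.tsv$", metadataPath))
    metadataPath <- paste0(sub("\\.tsv$", "", path), ".meta.tsv")
  X <- t(dosages(G))
  out <- data.frame(variant_id = variantIds(G), X, check.names = FALSE)
  colnames(out) <- c("variant_id", rownames(dosages(G)))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  md <- data.frame(id = variantIds(G), position = variantPositions(G),
                   maf = mafs(G))
  write.table(md, metadataPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(path, metadataPath))
}
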