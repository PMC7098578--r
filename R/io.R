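#' Read and write genotype panels as TSV matrix + map
#'
#' The matrix file is markers-in-columns with a leading `genotype` column;
#' the map file has columns `marker`, `chrom`, `pos`.
#'
#' @param panel a `gv_panel`.
#' @param matrix_path,map_path file paths.
#' @return `write_genotypes_tsv` returns the paths invisibly;
#'   `read_genotypes_tsv` returns a `gv_panel`.
#' @export
write_genotypes_tsv <- function(panel, matrix_path, map_path) {
  stopifnot(inherits(panel, "gv_panel"))
  dt <- data.table::as.data.table(panel$dosage, keep.rownames = "genotype")
  data.table::fwrite(dt, matrix_path, sep = "\t", na = "NA")
  data.table::fwrite(panel$map[, c("marker", "chrom", "pos")], map_path,
                     sep = "\t")
  invisible(c(matrix_path, map_path))
}

#' @rdname write_genotypes_tsv
#' @export
read_genotypes_tsv <- function(matrix_path, map_path) {
  dt <- data.table::fread(matrix_path, sep = "\t")
  map <- as.data.frame(data.table::fread(map_path, sep = "\t"))
  ids <- dt$genotype
  dos <- as.matrix(dt[, -1])
  rownames(dos) <- ids
  new_panel(dos, map)
}

#' Write a genotype panel as a minimal biallelic VCF
#'
#' Emits VCFv4.2 with GT calls only (`0/0`, `0/1`, `1/1`, `./.`), REF `A`
#' and ALT `T` placeholders, and contig headers from the panel's map.
#'
#' @param panel a `gv_panel`.
#' @param path output file path.
#' @export
write_genotypes_vcf <- function(panel, path) {
  stopifnot(inherits(panel, "gv_panel"))
  gt_codes <- c("0/0", "0/1", "1/1")
  dos <- panel$dosage
  gt <- matrix("./.", nrow(dos), ncol(dos))
  ok <- !is.na(dos)
  gt[ok] <- gt_codes[dos[ok] + 1L]
  chroms <- unique(panel$map$chrom)
  lens <- if (!is.null(panel$chrom_len)) panel$chrom_len[chroms]
          else tapply(panel$map$pos, panel$map$chrom, max)[chroms]
  header <- c("##fileformat=VCFv4.2",
              "##source=grainvar",
              sprintf("##contig=<ID=%s,length=%d>", chroms,
                      as.integer(lens)),
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                      "FILTER", "INFO", "FORMAT", rownames(dos)),
                    collapse = "\t"))
  body <- data.table::data.table(
    CHROM = panel$map$chrom, POS = panel$map$pos, ID = panel$map$marker,
    REF = "A", ALT = "T", QUAL = ".", FILTER = "PASS", INFO = ".",
    FORMAT = "GT")
  body <- cbind(body, data.table::as.data.table(t(gt)))
  writeLines(header, path)
  data.table::fwrite(body, path, sep = "\t", append = TRUE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a biallelic VCF into a genotype panel
#'
#' Uses `VariantAnnotation::readVcf`; dosages count the ALT allele.
#'
#' @param path VCF file path.
#' @return a `gv_panel`.
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("reading VCF requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  dos[gt %in% c("0/0", "0|0")] <- 0L
  dos[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  dos[gt %in% c("1/1", "1|1")] <- 2L
  rr <- SummarizedExperiment::rowRanges(vcf)
  map <- data.frame(marker = rownames(gt),
                    chrom = as.character(GenomicRanges::seqnames(rr)),
                    pos = GenomicRanges::start(rr),
                    stringsAsFactors = FALSE)
  new_panel(t(dos), map)
}

#' Export QTL intervals as BED
#'
#' 0-based half-open intervals, one row per QTL.
#'
#' @param qtl QTL table from [build_qtl()].
#' @param path output path.
#' @export
write_qtl_bed <- function(qtl, path) {
  bed <- data.frame(chrom = qtl$chrom,
                    start = as.integer(qtl$start - 1),
                    end = as.integer(qtl$end),
                    name = paste0("QTL", qtl$qtl))
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
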