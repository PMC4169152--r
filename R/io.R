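#' Read and write the tab-delimited exchange formats
#'
#' Genotypes travel as a lines x markers table of 0/1/2 calls with NA for
#' missing; the genetic map as (marker, chrom, pos_cM); phenotypes as
#' (line, value); pedigrees as (line_id, family_id, generation, parent_id)
#' plus an \code{ssd_generations} header comment; cross plans as one table
#' per tier. All files are plain tab-separated text with a header row.
#'
#' @param geno Genotype matrix.
#' @param path File path.
#' @name magic_io
NULL

#' @rdname magic_io
#' @export
write_genotypes <- function(geno, path) {
  df <- data.frame(line = rownames(geno), geno, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname magic_io
#' @export
read_genotypes <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1L]]
  m
}

#' @rdname magic_io
#' @param map Genetic map data.frame.
#' @export
write_map <- function(map, path) {
  utils::write.table(map[, c("marker", "chrom", "pos_cM")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
}

#' @rdname magic_io
#' @export
read_map <- function(path) {
  utils::read.delim(path, colClasses = c("character", "character", "numeric"),
                    stringsAsFactors = FALSE)
}

#' @rdname magic_io
#' @param phenotype Named vector over lines.
#' @export
write_phenotype <- function(phenotype, path) {
  utils::write.table(data.frame(line = names(phenotype), value = unname(phenotype)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname magic_io
#' @export
read_phenotype <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(df$value, df$line)
}

#' @rdname magic_io
#' @param pedigree A \code{magic_pedigree}.
#' @export
write_pedigree <- function(pedigree, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# ssd_generations=%d", attr(pedigree, "ssd_generations")), con)
  utils::write.table(as.data.frame(pedigree), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' @rdname magic_io
#' @export
read_pedigree <- function(path) {
  first <- readLines(path, n = 1L)
  t <- as.integer(sub(".*ssd_generations=", "", first))
  ped <- utils::read.delim(path, skip = 1L, stringsAsFactors = FALSE)
  attr(ped, "ssd_generations") <- t
  class(ped) <- c("magic_pedigree", "data.frame")
  ped
}

#' @rdname magic_io
#' @param plan A \code{cross_plan}.
#' @param prefix Output path prefix; writes \code{<prefix>_twoways.tsv},
#'   \code{<prefix>_fourways.tsv}, \code{<prefix>_eightways.tsv}.
#' @export
write_cross_plan <- function(plan, prefix) {
  utils::write.table(plan$twoways, paste0(prefix, "_twoways.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(plan$fourways, paste0(prefix, "_fourways.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(plan$eightways, paste0(prefix, "_eightways.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' @rdname magic_io
#' @param scan A \code{magic_scan}.
#' @export
write_scan <- function(scan, path) {
  utils::write.table(scan$result, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}
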