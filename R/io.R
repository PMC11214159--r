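# Readers and writers for the plain-text formats the pipeline consumes and
# emits.  FASTA goes through Biostrings; minimal VCF through vcfR; GFF3
# masks through rtracklayer.  Generated files carry their seed/parameters in
# headers and round-trip losslessly.

#' Read an aligned FASTA file
#'
#' @param path file path.
#' @return named character vector of upper-case sequences; names keep the
#'   full header line.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- names(ss)
  out
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param info optional named list appended as `key=value` tokens to the
#'   first record's header (seed/parameter provenance).
#' @export
write_fasta <- function(seqs, path, info = NULL) {
  nm <- names(seqs)
  if (!is.null(info) && length(seqs))
    nm[1] <- paste(nm[1], paste(names(info), unlist(info), sep = "=",
                                collapse = " "))
  ss <- Biostrings::BStringSet(unname(seqs))
  names(ss) <- nm
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write a haplotype set (samples + ancestral) as FASTA
#'
#' The ancestral record is named `ancestral` and the generator's seed and
#' parameters are recorded on its header line.
#'
#' @param x a `haplotype_set` from [gen_neutral_locus()] /
#'   [gen_sweep_locus()].
#' @param path output path.
#' @export
write_haplotype_fasta <- function(x, path) {
  seqs <- c(structure(x$ancestral, names = "ancestral"), x$sequences)
  info <- c(list(seed = x$seed),
            x$params[!vapply(x$params, is.na, logical(1))])
  write_fasta(seqs, path, info = info)
}

#' Read a haplotype alignment with a designated ancestral record
#'
#' @param path FASTA path.
#' @param ancestral_id name of the ancestral/outgroup record (first
#'   whitespace-separated token of the header).
#' @return a [haplotype_window()].
#' @export
read_haplotype_fasta <- function(path, ancestral_id = "ancestral") {
  seqs <- read_fasta(path)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[[`, character(1), 1L)
  anc <- which(ids == ancestral_id)
  if (length(anc) != 1L)
    stop("input error: expected exactly one record named '",
         ancestral_id, "'")
  samples <- seqs[-anc]
  names(samples) <- ids[-anc]
  haplotype_window(samples, unname(seqs[anc]))
}

#' Read a minimal VCF (CHROM, POS, REF, ALT, GT)
#'
#' Multi-allelic records are skipped with a warning (infinite-sites
#' pipeline).  Diploid genotypes are expanded to two haplotype rows per
#' sample; set `require_phased = TRUE` to fail on `/`-separated genotypes.
#'
#' @param path VCF path (uncompressed).
#' @param require_phased fail on unphased diploid records.
#' @return list with `pos` (1-based POS), `ref`, `alt`, and `haplotypes`
#'   (haplotype x site matrix of 0/1 allele indices, NA for missing).
#' @export
read_vcf_minimal <- function(path, require_phased = FALSE) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_vcf_minimal() needs the vcfR package")
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)))              # single-record VCF gives a bare vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt)
  if (any(multi))
    warning(sum(multi), " multi-allelic record(s) skipped")
  gt <- vcfR::extract.gt(v, element = "GT")
  keep <- which(!multi)
  gt <- gt[keep, , drop = FALSE]
  if (require_phased && any(grepl("/", gt, fixed = TRUE), na.rm = TRUE))
    stop("input error: unphased genotypes present")
  hap <- do.call(rbind, lapply(seq_len(ncol(gt)), function(j) {
    al <- strsplit(ifelse(is.na(gt[, j]), ".", gt[, j]), "[/|]")
    k <- max(lengths(al))
    m <- t(vapply(al, function(a)
      suppressWarnings(as.integer(rep_len(a, k))), integer(k)))
    rownames(m) <- NULL
    t(m)
  }))
  list(pos = as.integer(fix[keep, "POS"]),
       ref = fix[keep, "REF"], alt = alt[keep],
       haplotypes = hap)
}

#' Read a GFF3 coding-feature mask
#'
#' @param path GFF3 path.
#' @param feature feature types to mask (default CDS/exon).
#' @return data.frame of 0-based half-open `start`, `end` ranges suitable
#'   for [alignment_block()]'s `mask`.
#' @export
read_gff3_mask <- function(path, feature = c("CDS", "exon")) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("read_gff3_mask() needs the rtracklayer package")
  gr <- as.data.frame(rtracklayer::import(path))
  gr <- gr[as.character(gr$type) %in% feature, , drop = FALSE]
  data.frame(start = gr$start - 1L, end = gr$end)
}

#' Write a BED6+ window track
#'
#' Coordinates are 0-based half-open; floats are written at 6 significant
#' digits; a `#` header line records provenance.
#'
#' @param df data.frame with `start`, `end` and numeric extra columns (for
#'   example a [sliding_scan()] track).
#' @param path output path.
#' @param chrom chromosome/locus name for column 1.
#' @param name_prefix feature-name prefix for column 4.
#' @param header provenance string for the `#` comment line.
#' @export
write_bed <- function(df, path, chrom = "locus", name_prefix = "win",
                      header = NULL) {
  stopifnot(all(df$start < df$end))
  extras <- df[, setdiff(names(df), c("start", "end")), drop = FALSE]
  num <- vapply(extras, is.numeric, logical(1))
  extras[num] <- lapply(extras[num], signif, digits = 6)
  bed <- data.frame(chrom = chrom, start = df$start, end = df$end,
                    name = sprintf("%s%04d", name_prefix,
                                   seq_len(nrow(df))),
                    score = 0, strand = ".", extras)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# sweepfoot ",
                    as.character(utils::packageVersion("sweepfoot")),
                    if (!is.null(header)) paste0(" | ", header) else ""),
             con)
  utils::write.table(bed, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read the BC1 genotype/map/phenotype CSV triplet
#'
#' Genotype CSV: rows = individuals, columns = markers, codes `b`/`h`
#' (anything else missing).  Map CSV: `marker,lg,pos`.  Phenotype CSV:
#' numeric trait columns.  `#` lines are comments.
#'
#' @param geno_csv,map_csv,pheno_csv file paths.
#' @return a [cross_data()].
#' @export
read_cross_csv <- function(geno_csv, map_csv, pheno_csv) {
  g <- utils::read.csv(geno_csv, comment.char = "#", row.names = 1,
                       check.names = FALSE, colClasses = "character")
  m <- utils::read.csv(map_csv, comment.char = "#")
  p <- utils::read.csv(pheno_csv, comment.char = "#", row.names = 1)
  cross_data(as.matrix(g), m, p)
}

#' Write a BC1 cross as the genotype/map/phenotype CSV triplet
#'
#' @param cross a [cross_data()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @param header provenance comment written to each file.
#' @return named character vector of the three paths.
#' @export
write_cross_csv <- function(cross, dir, prefix = "bc1", header = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, "_",
                                 c("geno", "map", "pheno"), ".csv"))
  hline <- paste0("# sweepfoot",
                  if (!is.null(header)) paste0(" | ", header) else "")
  wr <- function(x, path, rn) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hline, con)
    utils::write.table(x, con, sep = ",", quote = FALSE,
                       row.names = rn, col.names = NA_or_names(rn, x))
  }
  NA_or_names <- function(rn, x) if (rn) NA else TRUE
  g <- as.data.frame(cross$genotypes)
  g[is.na(g)] <- "-"
  rownames(g) <- sprintf("ind%03d", seq_len(nrow(g)))
  wr(g, paths[1], TRUE)
  wr(cross$map, paths[2], FALSE)
  ph <- cross$phenotypes
  rownames(ph) <- rownames(g)
  wr(ph, paths[3], TRUE)
  names(paths) <- c("geno", "map", "pheno")
  invisible(paths)
}
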