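# TSV readers/writers for every interface format. All tables are written
# with header rows, tab separation, no quoting, "." for missing values;
# intensity matrices carry the probe ids in a leading probe_id column.

write_tsv <- function(df, path) {
  df[] <- lapply(df, function(x) ifelse(is.na(x), ".", as.character(x)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, check.names = FALSE, na.strings = ".",
             stringsAsFactors = FALSE)
}

#' Read / write an intensity matrix TSV
#'
#' First column `probe_id`, remaining columns one per sample. Duplicated
#' probe ids are rejected by name.
#'
#' @param mat numeric matrix with probe rownames and sample colnames.
#' @param path file path.
#' @return `read_matrix_tsv()`: the matrix.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(probe_id = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  dup <- df$probe_id[duplicated(df$probe_id)]
  if (length(dup)) stopf("duplicated probe id in %s: %s", path, dup[1])
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$probe_id
  m
}

#' Read / write gene models as BED12
#'
#' Gene models travel as BED12 (0-based half-open, blocks = exons) through
#' `rtracklayer`. `read_bed12()` returns the internal representation: a
#' `GRanges` with metadata `name` (gene symbol) and `exons` (absolute
#' 1-based `IRangesList`).
#'
#' @param gene_models `GRanges` with `name` and `exons` metadata.
#' @param path file path.
#' @return `read_bed12()`: the gene-model `GRanges`.
#' @export
write_bed12 <- function(gene_models, path) {
  exons <- S4Vectors::mcols(gene_models)$exons
  grl <- methods::as(lapply(seq_along(gene_models), function(i) {
    GenomicRanges::GRanges(
      seqnames = GenomicRanges::seqnames(gene_models)[i],
      ranges = exons[[i]],
      strand = GenomicRanges::strand(gene_models)[i])
  }), "GRangesList")
  names(grl) <- S4Vectors::mcols(gene_models)$name
  rtracklayer::export(rtracklayer::asBED(grl), path, format = "bed")
  invisible(path)
}

#' @rdname write_bed12
#' @export
read_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  exons <- IRanges::shift(S4Vectors::mcols(gr)$blocks,
                          GenomicRanges::start(gr) - 1L)
  out <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(gr),
    ranges = IRanges::ranges(gr),
    strand = GenomicRanges::strand(gr))
  S4Vectors::mcols(out)$name <- S4Vectors::mcols(gr)$name
  S4Vectors::mcols(out)$exons <- exons
  out
}

#' Load a two-channel array set from TSV files
#'
#' Reads both channel matrices, the sample sheet and the probe annotation,
#' enforces row/column alignment (the supernatant matrix is reordered to
#' match the IP matrix if needed), identifies spike-ins from the annotation,
#' and floors intensities.
#'
#' @param ip_path,sup_path intensity matrix TSVs.
#' @param samples_path sample sheet TSV (sample_id, group, replicate).
#' @param annotation_path probe annotation TSV.
#' @param floor intensity floor.
#' @return a [two_channel_set()] carrying the annotation.
#' @export
read_two_channel <- function(ip_path, sup_path, samples_path,
                             annotation_path, floor = 1) {
  ip <- read_matrix_tsv(ip_path)
  sup <- read_matrix_tsv(sup_path)
  if (!setequal(rownames(ip), rownames(sup)) ||
      !setequal(colnames(ip), colnames(sup)))
    stopf("IP and supernatant matrices cover different probes or samples")
  sup <- sup[rownames(ip), colnames(ip), drop = FALSE]
  samples <- read_tsv(samples_path)
  annotation <- read_tsv(annotation_path)
  missing <- setdiff(rownames(ip), annotation$probe_id)
  if (length(missing))
    stopf("probe missing from annotation: %s", missing[1])
  spike <- annotation$probe_id[annotation$rna_class == "spikein"]
  spike <- intersect(spike, rownames(ip))
  annotation <- annotation[match(rownames(ip), annotation$probe_id), ]
  two_channel_set(ip, sup, samples, spike, annotation = annotation,
                  floor = floor)
}

#' Write a simulated dataset to a directory
#'
#' Emits the full external interface: `annotation.tsv`, `gene_models.bed`
#' (BED12), `gene_sets.gmt`, `ip_intensity.tsv`, `sup_intensity.tsv`,
#' `samples.tsv`, `lnc_context.tsv` and `ground_truth.json`. Output is
#' byte-identical for identical config + seed.
#'
#' @param sim a [simulate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_tsv(sim$annotation, p("annotation.tsv"))
  write_bed12(sim$gene_models, p("gene_models.bed"))
  write_gmt(sim$gene_sets, p("gene_sets.gmt"))
  write_matrix_tsv(sim$arrays$ip, p("ip_intensity.tsv"))
  write_matrix_tsv(sim$arrays$sup, p("sup_intensity.tsv"))
  write_tsv(sim$arrays$samples, p("samples.tsv"))
  write_tsv(sim$lnc_context, p("lnc_context.tsv"))
  truth <- sim$truth
  gt <- list(
    seed = sim$config$seed,
    effects = truth$effects,
    spike_log2 = truth$spike_log2,
    m_true = data.frame(transcript_id = rownames(truth$m_true),
                        truth$m_true, check.names = FALSE),
    log2_abund = data.frame(transcript_id = rownames(truth$log2_abund),
                            truth$log2_abund, check.names = FALSE))
  jsonlite::write_json(gt, p("ground_truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir dataset directory.
#' @param floor intensity floor for [read_two_channel()].
#' @return list: `arrays` (two_channel_set with annotation), `annotation`,
#'   `gene_models`, `gene_sets`, `lnc_context`.
#' @export
read_dataset <- function(dir, floor = 1) {
  p <- function(f) file.path(dir, f)
  arrays <- read_two_channel(p("ip_intensity.tsv"), p("sup_intensity.tsv"),
                             p("samples.tsv"), p("annotation.tsv"),
                             floor = floor)
  list(arrays = arrays, annotation = arrays$annotation,
       gene_models = read_bed12(p("gene_models.bed")),
       gene_sets = read_gmt(p("gene_sets.gmt")),
       lnc_context = read_tsv(p("lnc_context.tsv")))
}

#' Read a pipeline run configuration from YAML
#'
#' Flat key-value YAML mapping onto the `config` argument of
#' [run_pipeline()].
#'
#' @param path YAML file.
#' @return named list.
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}
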