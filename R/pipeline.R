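# End-to-end orchestration: simulate -> align -> map -> genotype ->
# evaluate, with a single config, per-purpose seeds, optional region
# splitting for the genotyping stage, and a machine-readable run manifest.

#' Default pipeline configuration
#'
#' All parameters of every stage with their defaults, as a nested list
#' that can be written/read as YAML. Override any subset via `...` (named
#' top-level blocks) or by editing the returned list.
#'
#' @param ... Named blocks replacing defaults, e.g.
#'   `template = list(unit_length = 5000)`.
#' @return A `run_config` list.
#' @export
#' @examples
#' cfg <- default_config(template = list(unit_length = 2000, copies = 2))
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    template = list(unit_length = 10000L, copies = 2L,
                    inter_copy_divergence = 0.05, gc_fraction = 0.4),
    variants = list(het_rate = 5e-4, hom_rate = 5e-4),
    reads = list(coverage = 50, read_len = 36L, insert_mean = 250,
                 insert_sd = 30, error_rate = 0.001),
    align = list(k = 2L, insert_range = c(150L, 300L)),
    map = list(strategy = "all", d_cap = 200L),
    model = list(e = 3e-4, lambda = 0.67, theta = 0.001, q_threshold = 40,
                 max_q = 255, degeneracy_correction = TRUE,
                 multilocus = TRUE),
    regions = NULL,
    out_dir = NULL)
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
      for (k in names(over[[nm]])) cfg[[nm]][[k]] <- over[[nm]][[k]]
    } else cfg[[nm]] <- over[[nm]]
  }
  structure(cfg, class = "run_config")
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file.
#' @param config A `run_config`.
#' @return `read_config` returns a `run_config`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(default_config, cfg)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  with(cfg, {
    stopifnot(template$unit_length >= 1, template$copies >= 1,
              reads$coverage > 0, align$k >= 0,
              map$strategy %in% c("uni", "bestno", "best", "all"))
  })
  if (!is.null(cfg$regions)) {
    r <- rbindlist(lapply(cfg$regions, as.data.table))
    setorder(r, rname, start)
    if (any(r$start < 0 | r$end <= r$start)) stop("invalid region bounds")
    if (nrow(r) > 1) {
      same <- r$rname[-1] == r$rname[-nrow(r)]
      if (any(same & r$start[-1] < r$end[-nrow(r)]))
        stop("regions overlap")
    }
  }
  invisible(cfg)
}

#' Run the full pipeline
#'
#' Builds the template, injects variation, samples paired-end reads,
#' aligns, applies the mapping strategy, genotypes (optionally split by
#' region; reads contributing to several regions are handed to each, so a
#' partition of the genome reproduces the unpartitioned calls exactly),
#' flags significant SNPs and, having the truth in hand, evaluates. When
#' `config$out_dir` is set, writes FASTA/FASTQ/SAM/truth/calls/VCF/metrics
#' plus `manifest.json` (parameters, seed, file checksums).
#'
#' @param config A `run_config` from [default_config()]/[read_config()].
#' @return List with `genome`, `sample`, `reads`, `alnset`, `map`,
#'   `genotypes` (after [call_variants()]), `confusion`, `metrics`,
#'   and `paths` (when files were written).
#' @export
run_pipeline <- function(config = default_config()) {
  validate_config(config)
  seed <- config$seed
  genome <- build_template(
    unit_length = config$template$unit_length,
    copies = config$template$copies,
    inter_copy_divergence = config$template$inter_copy_divergence,
    gc_fraction = config$template$gc_fraction, seed = seed)
  sample <- inject_variation(genome, config$variants$het_rate,
                             config$variants$hom_rate, seed = seed)
  reads <- sample_pe_reads(sample, coverage = config$reads$coverage,
                           read_len = config$reads$read_len,
                           insert_mean = config$reads$insert_mean,
                           insert_sd = config$reads$insert_sd,
                           error_rate = config$reads$error_rate,
                           seed = seed)
  alnset <- align_reads(reads, genome, k = config$align$k,
                        insert_range = config$align$insert_range)
  map <- apply_strategy(alnset, config$map$strategy,
                        d_cap = config$map$d_cap, seed = seed)
  params <- do.call(model_params, config$model)
  pu <- build_pileups(map, genome)
  regions <- config$regions
  gt <- if (is.null(regions)) {
    genotype_pileups(pu, genome, params)
  } else {
    parts <- lapply(regions, function(r)
      genotype_pileups(pu, genome, params, region = r))
    posts <- do.call(rbind, lapply(parts, attr, "posterior"))
    out <- rbindlist(parts)
    data.table::setattr(out, "posterior", posts)
    data.table::setattr(out, "class", c("genotype_table", class(out)))
    out[]
  }
  calls <- call_variants(gt, params)
  cc <- classify_calls(calls, sample$truth)
  mt <- metrics(cc)
  paths <- NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    pth <- function(f) file.path(config$out_dir, f)
    paths <- c(
      ref = write_fasta(genome, pth("reference.fasta")),
      truth = write_truth(sample$truth, pth("truth.tsv")),
      fastq = write_fastq(reads, pth("reads"))[1],
      sam = write_sam(map, genome, pth("alignments.sam")),
      calls = write_calls_tsv(calls, pth("calls.tsv")),
      vcf = write_vcf(calls, genome, pth("calls.vcf")))
    metrics_dt <- data.table(metric = c("TP", "TN", "FP", "FN", "TPFG",
                                        "TPR", "FPR", "FDR", "accuracy"),
                             value = c(cc$TP, cc$TN, cc$FP, cc$FN, cc$TPFG,
                                       mt$TPR, mt$FPR, mt$FDR, mt$accuracy))
    write.table(metrics_dt, pth("metrics.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- c(paths, metrics = pth("metrics.tsv"))
    manifest <- list(
      package = "paracall",
      version = as.character(utils::packageVersion("paracall")),
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      config = unclass(config),
      checksums = as.list(vapply(paths, function(p)
        unname(tools::md5sum(p)), "")))
    jsonlite::write_json(manifest, pth("manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    paths <- c(paths, manifest = pth("manifest.json"))
  }
  list(genome = genome, sample = sample, reads = reads, alnset = alnset,
       map = map, genotypes = calls, confusion = cc, metrics = mt,
       paths = paths)
}

#' Split a genome into non-overlapping regions
#'
#' Convenience for region-parallel genotyping: tiles every sequence into
#' windows of at most `width` loci (0-based, half-open).
#'
#' @param genome A [ref_genome()].
#' @param width Window width in nt.
#' @return List of `list(rname, start, end)` blocks.
#' @export
tile_regions <- function(genome, width) {
  genome <- as_ref_genome(genome)
  out <- list()
  for (sn in names(genome$sequences)) {
    L <- nchar(genome$sequences[[sn]])
    starts <- seq(0L, L - 1L, by = width)
    for (s in starts)
      out[[length(out) + 1L]] <- list(rname = sn, start = s,
                                      end = min(s + width, L))
  }
  out
}
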