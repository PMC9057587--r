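#' Synthetic per-residue annotation table
#'
#' Stands in for a structure-derived annotation in fully synthetic runs
#' (labelled synthetic; no real structure is emulated). Epitope positions
#' are drawn well-exposed and free of disulfides, as antibody-accessible
#' surface residues must be; `buried_positions` get `rsa = buried_rsa` and
#' `disulfide_positions` are flagged bonded; all remaining positions draw
#' RSA uniformly over a realistic surface range.
#'
#' @param ref a [reference_construct()].
#' @param epitope_positions positions guaranteed exposed (rsa in 0.35..0.9).
#' @param buried_positions positions annotated buried.
#' @param disulfide_positions positions annotated disulfide-bonded (should
#'   be cysteines in `ref`; a warning is emitted otherwise).
#' @param buried_rsa RSA assigned to buried positions (default 0.02).
#' @param seed RNG seed.
#' @return annotation data.frame (`position`, `rsa`, `disulfide`).
#' @export
synthetic_annotation <- function(ref, epitope_positions,
                                 buried_positions = integer(),
                                 disulfide_positions = integer(),
                                 buried_rsa = 0.02, seed = 1L) {
  pos <- native_positions(ref)
  stopifnot(all(c(epitope_positions, buried_positions,
                  disulfide_positions) %in% pos))
  aa <- strsplit(ref$aa_seq, "", fixed = TRUE)[[1L]]
  if (length(disulfide_positions) &&
      any(aa[match(disulfide_positions, pos)] != "C"))
    warning("disulfide annotation on non-cysteine construct position(s)")
  set.seed(seed)
  rsa <- stats::runif(length(pos), 0.05, 0.9)
  rsa[pos %in% epitope_positions] <-
    stats::runif(sum(pos %in% epitope_positions), 0.35, 0.9)
  rsa[pos %in% buried_positions] <- buried_rsa
  data.frame(position = pos, rsa = round(rsa, 4L),
             disulfide = pos %in% disulfide_positions)
}

#' Recovery of planted epitope positions
#'
#' Sensitivity `|called n truth| / |truth|` and precision
#' `|called n truth| / |called|`. An empty call set gives precision 1 when
#' the truth is also empty, otherwise precision 0 with `flag =
#' "empty_call_set"`.
#'
#' @param called integer vector of called (or filtered) positions.
#' @param truth integer vector of true epitope positions.
#' @return list with `sensitivity`, `precision`, `n_called`, `n_truth`,
#'   `flag`.
#' @export
evaluate_recovery <- function(called, truth) {
  called <- unique(as.integer(called))
  truth <- unique(as.integer(truth))
  tp <- length(intersect(called, truth))
  sens <- if (length(truth) == 0L) 1 else tp / length(truth)
  if (length(called) == 0L) {
    prec <- if (length(truth) == 0L) 1 else 0
    flag <- if (length(truth) == 0L) "" else "empty_call_set"
  } else {
    prec <- tp / length(called)
    flag <- ""
  }
  list(sensitivity = sens, precision = prec,
       n_called = length(called), n_truth = length(truth), flag = flag)
}

# Deterministic fan-out of the run seed into independent stage seeds
# (kept below 2^31 - 1).
stage_seed <- function(seed, stage) {
  stages <- c(reference = 1L, mutagenize = 2L, select = 3L,
              seq_selected = 4L, seq_unselected = 5L, annotation = 6L)
  if (!stage %in% names(stages)) stop("unknown stage '", stage, "'")
  as.integer((as.numeric(seed) * 1009 + stages[[stage]]) %% 2147483647)
}

default_config <- function() {
  list(
    seed = 1L,
    outdir = "epimapr_run",
    reference = list(fasta = NULL, n_aa = 111L, first_residue = 22L),
    simulate = list(
      epitope_positions = c(62L, 75L, 110L, 111L, 112L),
      decoy_buried = integer(), decoy_disulfide = integer(),
      n_clones = 50000L, lambda_nt = 2, rounds = 2L,
      q_effect = 0.8, p_hit = 0.9, p_bg = 0.005,
      target_size = NULL, coverage = 200, read_length = 150L,
      error_rate = 0.001),
    reads = list(selected = NULL, unselected = NULL),
    count = list(k = 15L, max_mismatch = 10L, min_coverage = 20L,
                 search_rc = FALSE),
    enrich = list(threshold = 2, pseudocount = 0),
    filter = list(annotation = NULL, structure = NULL, chain = "A",
                  rsa_min = 0.15, drop_unannotated = FALSE))
}

merge_config <- function(base, user, path = "") {
  for (key in names(user)) {
    full <- if (path == "") key else paste0(path, "$", key)
    if (!key %in% names(base)) stop("unknown config key: ", full)
    if (is.list(base[[key]]) && !is.null(user[[key]]) && is.list(user[[key]]))
      base[[key]] <- merge_config(base[[key]], user[[key]], full)
    else base[[key]] <- user[[key]]
  }
  base
}

#' Validate and complete a run configuration
#'
#' Unknown keys are rejected; omitted keys take documented defaults.
#' `config` may be a list or the path to a YAML file. Either the `simulate`
#' block is active (default) or both `reads$selected` and `reads$unselected`
#' point at FASTQ files, in which case `reference$fasta` is required.
#'
#' @param config list or YAML path.
#' @return the completed config list.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  cfg <- merge_config(default_config(), config)
  use_reads <- !is.null(cfg$reads$selected) || !is.null(cfg$reads$unselected)
  if (use_reads) {
    if (is.null(cfg$reads$selected) || is.null(cfg$reads$unselected))
      stop("reads mode needs both reads$selected and reads$unselected")
    if (is.null(cfg$reference$fasta))
      stop("reads mode needs reference$fasta")
    for (p in c(cfg$reads$selected, cfg$reads$unselected,
                cfg$reference$fasta))
      if (!file.exists(p)) stop("input file not found: ", p)
  }
  sim <- cfg$simulate
  stopifnot(sim$lambda_nt >= 0, sim$rounds >= 1, sim$coverage > 0,
            sim$q_effect >= 0, sim$q_effect <= 1,
            sim$p_bg >= 0, sim$p_bg <= sim$p_hit, sim$p_hit <= 1,
            cfg$enrich$threshold >= 0, cfg$filter$rsa_min >= 0)
  cfg$mode <- if (use_reads) "reads" else "simulate"
  cfg
}

#' Run the full epitope-mapping pipeline
#'
#' Executes simulate (or read loading) -> count -> enrich -> filter ->
#' evaluate, writing every artifact under `config$outdir`: `ref.fasta`,
#' `selected.fastq`, `unselected.fastq`, `truth.tsv`, `annotation.tsv`
#' (simulate mode), `counts_selected.tsv`, `counts_unselected.tsv`,
#' `enrichment.tsv`, `epitope.tsv`, `report.tsv`, `run.log`. The log records
#' every parameter actually used. The single run seed fans out into fixed
#' per-stage seeds so stages are independently reproducible.
#'
#' @param config list or YAML path, see [validate_config()].
#' @return (invisibly) a list: `config`, `paths`, `ref`, `counts`, `etab`,
#'   `epitope` (the filtered `epitope_set`), `called`, `recovery` (simulate
#'   mode), `truth`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- validate_config(config)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  logf <- file.path(cfg$outdir, "run.log")
  logl <- character()
  note <- function(...) logl <<- c(logl, paste0(...))
  note("epimapr run, seed=", cfg$seed, ", mode=", cfg$mode)
  note(gsub("\n", " ", paste(utils::capture.output(utils::str(cfg)),
                             collapse = " | ")))

  truth <- NULL
  if (cfg$mode == "simulate") {
    sim <- cfg$simulate
    decoys <- sort(unique(c(sim$decoy_buried, sim$decoy_disulfide)))
    if (is.null(cfg$reference$fasta)) {
      ref <- random_reference(cfg$reference$n_aa, cfg$reference$first_residue,
                              seed = stage_seed(cfg$seed, "reference"),
                              cys_positions = sim$decoy_disulfide)
    } else ref <- read_reference(cfg$reference$fasta)
    paths$ref <- file.path(cfg$outdir, "ref.fasta")
    write_reference(ref, paths$ref)
    target <- if (is.null(sim$target_size)) sim$n_clones else sim$target_size
    params <- selection_params(c(sim$epitope_positions, decoys),
                               q_effect = sim$q_effect, p_hit = sim$p_hit,
                               p_bg = sim$p_bg, rounds = sim$rounds)
    lib <- mutagenize_library(ref, sim$n_clones, sim$lambda_nt,
                              seed = stage_seed(cfg$seed, "mutagenize"))
    sel <- select_library(lib, params, target_size = target,
                          seed = stage_seed(cfg$seed, "select"))
    reads_sel <- sequence_library(sel, sim$coverage, sim$read_length,
                                  sim$error_rate,
                                  seed = stage_seed(cfg$seed, "seq_selected"))
    reads_uns <- sequence_library(lib, sim$coverage, sim$read_length,
                                  sim$error_rate,
                                  seed = stage_seed(cfg$seed, "seq_unselected"))
    paths$selected <- file.path(cfg$outdir, "selected.fastq")
    paths$unselected <- file.path(cfg$outdir, "unselected.fastq")
    write_fastq(reads_sel, paths$selected)
    write_fastq(reads_uns, paths$unselected)
    truth <- ground_truth(sim$epitope_positions, params, sim$lambda_nt,
                          cfg$seed, decoy_positions = decoys)
    paths$truth <- file.path(cfg$outdir, "truth.tsv")
    write_truth(truth, paths$truth)
    if (is.null(cfg$filter$annotation) && is.null(cfg$filter$structure)) {
      ann <- synthetic_annotation(ref, sim$epitope_positions,
                                  buried_positions = sim$decoy_buried,
                                  disulfide_positions = sim$decoy_disulfide,
                                  seed = stage_seed(cfg$seed, "annotation"))
      paths$annotation <- file.path(cfg$outdir, "annotation.tsv")
      write_annotation(ann, paths$annotation)
      cfg$filter$annotation <- paths$annotation
    }
    note("simulated: ", sim$n_clones, " clones, lambda_nt=", sim$lambda_nt,
         ", rounds=", sim$rounds, ", epitope={",
         paste(sim$epitope_positions, collapse = ","), "}, decoys={",
         paste(decoys, collapse = ","), "}")
  } else {
    ref <- read_reference(cfg$reference$fasta)
    paths$selected <- cfg$reads$selected
    paths$unselected <- cfg$reads$unselected
  }

  counts <- list()
  for (libname in c("selected", "unselected")) {
    res <- count_library(read_fastq(paths[[libname]]), ref, libname,
                         k = cfg$count$k,
                         max_mismatch = cfg$count$max_mismatch,
                         search_rc = cfg$count$search_rc,
                         min_coverage = cfg$count$min_coverage)
    counts[[libname]] <- res$counts
    p <- file.path(cfg$outdir, paste0("counts_", libname, ".tsv"))
    write_counts(res$counts, p)
    paths[[paste0("counts_", libname)]] <- p
    utils::write.table(res$substitutions,
                       file.path(cfg$outdir,
                                 paste0("substitutions_", libname, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    note("counted ", libname, ": ", res$n_accepted, "/", res$n_reads,
         " reads accepted; rejections: ",
         paste(sprintf("%s=%d", res$rejections$reason, res$rejections$Freq),
               collapse = ", "))
  }

  F <- frequency_matrix(counts, reference = "unselected")
  etab <- enrichment_table(F, threshold = cfg$enrich$threshold,
                           pseudocount = cfg$enrich$pseudocount)
  paths$enrichment <- file.path(cfg$outdir, "enrichment.tsv")
  write_enrichment(etab, paths$enrichment)
  called <- called_positions(etab, "selected")
  s <- attr(etab, "size_factors")
  note("size factors: ",
       paste(sprintf("%s=%.4f", names(s), s), collapse = ", "),
       "; called at threshold ", cfg$enrich$threshold, ": {",
       paste(called, collapse = ","), "}")

  ann <- if (!is.null(cfg$filter$structure)) {
    model <- parse_structure(cfg$filter$structure)
    annotate_structure(ref, model, cfg$filter$chain)
  } else read_annotation(cfg$filter$annotation)
  sel_rows <- etab[etab$library == "selected", , drop = FALSE]
  scores <- stats::setNames(sel_rows$e_log2, sel_rows$position)
  epi <- filter_epitope(called, ann, scores = scores,
                        rsa_min = cfg$filter$rsa_min,
                        drop_unannotated = cfg$filter$drop_unannotated)
  paths$epitope <- file.path(cfg$outdir, "epitope.tsv")
  utils::write.table(epi, paths$epitope, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  note("epitope set after structural filter (rsa_min=", cfg$filter$rsa_min,
       "): {", paste(epi$position[epi$kept], collapse = ","), "}; excluded: ",
       paste(sprintf("%d(%s)", epi$position[!epi$kept],
                     epi$reason[!epi$kept]), collapse = ", "))

  recovery <- NULL
  if (!is.null(truth)) {
    pre <- evaluate_recovery(called, truth$epitope_positions)
    post <- evaluate_recovery(epi$position[epi$kept], truth$epitope_positions)
    recovery <- list(pre_filter = pre, post_filter = post)
    rep <- data.frame(stage = c("pre_filter", "post_filter"),
                      sensitivity = c(pre$sensitivity, post$sensitivity),
                      precision = c(pre$precision, post$precision),
                      n_called = c(pre$n_called, post$n_called),
                      n_truth = c(pre$n_truth, post$n_truth),
                      flag = c(pre$flag, post$flag))
    paths$report <- file.path(cfg$outdir, "report.tsv")
    utils::write.table(rep, paths$report, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    note(sprintf("recovery vs truth: pre-filter sens=%.3f prec=%.3f; %s",
                 pre$sensitivity, pre$precision,
                 sprintf("post-filter sens=%.3f prec=%.3f",
                         post$sensitivity, post$precision)))
  }
  writeLines(logl, logf)
  paths$log <- logf
  invisible(list(config = cfg, paths = paths, ref = ref, counts = counts,
                 etab = etab, epitope = epi,
                 called = called, recovery = recovery, truth = truth))
}

#' Enrichment score vs position plot
#'
#' @param etab an `enrichment_table`.
#' @param library library to plot (default "selected").
#' @param threshold horizontal calling threshold line.
#' @return a ggplot object.
#' @export
plot_enrichment <- function(etab, library = "selected",
                            threshold = attr(etab, "threshold")) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_enrichment needs ggplot2")
  d <- etab[etab$library == library & is.finite(etab$e_log2), , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position, y = .data$e_log2,
                                  colour = .data$called)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = "native position", y = "log2 enrichment vs median",
                  colour = "called") +
    ggplot2::theme_minimal()
}
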