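#' Build a pipeline run configuration
#'
#' @param fasta multi-record FASTA of plastomes.
#' @param reference sample id used as alignment/calling reference.
#' @param out_dir output directory (created if absent).
#' @param groups optional sample-to-species TSV (see [read_group_map()]).
#' @param annotations optional GenBank/GFF3 annotations for the reference.
#' @param alignment optional precomputed aligned FASTA; when given the
#'   built-in aligner is bypassed.
#' @param seed seed for the bootstrap and any other randomness.
#' @param params nested list of per-stage parameter overrides:
#'   `ssr$min_copies`, `pi$window`, `pi$step`, `align$band`,
#'   `markers$product_range`, `markers$min_size_diff`, `markers$max_snps`
#'   (cap on SNPs tried for dCAPS design, default 50),
#'   `phylo$bootstrap_n`, `phylo$model`, `phylo$outgroup`,
#'   `structure$min_ir_len`, `pi$hotspot_threshold`.
#' @return list of class `run_config`.
#' @export
run_config <- function(fasta, reference, out_dir, groups = NULL,
                       annotations = NULL, alignment = NULL, seed = 1L,
                       params = list()) {
  cfg <- list(fasta = fasta, reference = reference, out_dir = out_dir,
              groups = groups, annotations = annotations,
              alignment = alignment, seed = as.integer(seed), params = params)
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param path JSON file with the same fields.
#' @export
load_run_config <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  do.call(run_config, x)
}

#' @noRd
validate_run_config <- function(cfg) {
  if (!file.exists(cfg$fasta)) stop(sprintf("input FASTA not found: %s", cfg$fasta))
  for (f in c("groups", "annotations", "alignment")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop(sprintf("configured %s file not found: %s", f, cfg[[f]]))
  }
  invisible(cfg)
}

#' Run the full comparative pipeline
#'
#' Executes, in dependency order: structure detection and canonicalization,
#' SSR scanning, multiple alignment, variant calling and classification,
#' diagnostic-variant detection, sliding-window Pi, InDel and dCAPS marker
#' design with in-silico validation, and a bootstrap NJ phylogeny. Any
#' stage failure is recorded and its dependents are skipped; outputs that
#' were already written stay valid. The manifest lists every output file
#' with its md5 checksum, so a rerun with the same config and seed can be
#' verified byte-identical.
#'
#' @param cfg a [run_config()] or path to its JSON form.
#' @param quiet suppress progress messages.
#' @return the manifest, invisibly: list with `stages` (status per stage),
#'   `outputs` (files + md5), `summary` (counts).
#' @export
run_all <- function(cfg, quiet = FALSE) {
  if (is.character(cfg)) cfg <- load_run_config(cfg)
  validate_run_config(cfg)
  p <- cfg$params
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  out_file <- function(name) file.path(cfg$out_dir, name)
  stages <- list()
  outputs <- character(0)
  summary <- list()
  state <- new.env(parent = emptyenv())
  run_stage <- function(name, needs, fun) {
    missing_dep <- needs[!vapply(needs, function(d)
      isTRUE(stages[[d]] == "ok"), logical(1))]
    if (length(missing_dep)) {
      stages[[name]] <<- sprintf("skipped (needs %s)",
                                 paste(missing_dep, collapse = ", "))
      say("stage %-10s skipped", name)
      return(invisible(NULL))
    }
    res <- tryCatch({ fun(); "ok" },
                    error = function(e) sprintf("failed: %s", conditionMessage(e)))
    stages[[name]] <<- res
    say("stage %-10s %s", name, res)
  }

  run_stage("read", character(0), function() {
    genomes <- read_sequences(cfg$fasta)
    if (!cfg$reference %in% names(genomes))
      stop(sprintf("reference '%s' absent from input", cfg$reference))
    if (!is.null(cfg$groups)) {
      gm <- read_group_map(cfg$groups)
      check_group_map(gm, names(genomes))
      for (id in names(genomes)) genomes[[id]]$species <-
          gm$group[match(id, gm$sample)]
      state$groups <- gm
    }
    if (!is.null(cfg$annotations)) {
      genomes[[cfg$reference]] <-
        read_annotations(genomes[[cfg$reference]], cfg$annotations)
    }
    state$genomes <- genomes
    summary$n_genomes <<- length(genomes)
  })

  run_stage("structure", "read", function() {
    min_ir <- p$structure$min_ir_len %||% 1000L
    canon <- lapply(state$genomes, function(g) {
      st <- detect_quadripartite(g, min_ir_len = min_ir)
      canonicalize(g, st)
    })
    state$genomes <- canon
    tab <- do.call(rbind, lapply(canon, function(g)
      data.frame(sample = g$id, length = length(g),
                 lsc = g$structure$lsc_len, irb = g$structure$ir_len,
                 ssc = g$structure$ssc_len, ira = g$structure$ir_len)))
    write_tsv(tab, out_file("structure.tsv"))
    outputs <<- c(outputs, out_file("structure.tsv"))
    ref <- canon[[cfg$reference]]
    if (!is.null(ref$annotations)) {
      write_tsv(junction_report(ref), out_file("junctions.tsv"))
      outputs <<- c(outputs, out_file("junctions.tsv"))
    }
  })

  run_stage("ssr", "structure", function() {
    config <- ssr_config(p$ssr$min_copies %||% c(10L, 5L, 5L, 4L, 3L, 3L))
    tabs <- lapply(state$genomes, function(g) {
      t <- scan_ssrs(g, config)
      if (nrow(t)) cbind(sample = g$id, t) else NULL
    })
    tab <- do.call(rbind, tabs)
    write_tsv(tab, out_file("ssr.tsv"))
    outputs <<- c(outputs, out_file("ssr.tsv"))
    summary$n_ssrs <<- if (is.null(tab)) 0L else nrow(tab)
  })

  run_stage("align", "structure", function() {
    aln <- if (!is.null(cfg$alignment)) {
      read_alignment(cfg$alignment, cfg$reference)
    } else {
      align_plastomes(state$genomes, cfg$reference,
                      band = p$align$band %||% 200L)
    }
    state$aln <- aln
    write_alignment(aln, out_file("alignment.fasta"))
    outputs <<- c(outputs, out_file("alignment.fasta"))
  })

  run_stage("variants", "align", function() {
    v <- call_variants(state$aln)
    ref <- state$genomes[[cfg$reference]]
    if (!is.null(ref$annotations) && nrow(ref$annotations))
      v <- classify_regions(v, ref$annotations, length(ref))
    state$variants <- v
    write_vcf(v, out_file("variants.vcf"))
    outputs <<- c(outputs, out_file("variants.vcf"))
    summary$n_snps <<- sum(v$kind == "SNP")
    summary$n_indels <<- sum(v$kind == "InDel")
    if (!is.null(state$groups)) {
      dv <- diagnostic_variants(v, state$groups)
      state$diagnostics <- dv
      write_tsv(as.data.frame(dv), out_file("diagnostic_variants.tsv"))
      outputs <<- c(outputs, out_file("diagnostic_variants.tsv"))
      summary$n_diagnostic <<- nrow(dv)
    }
  })

  run_stage("pi", "align", function() {
    conf <- pi_config(p$pi$window %||% 500L, p$pi$step %||% 250L)
    prof <- sliding_pi(state$aln, conf)
    ref <- state$genomes[[cfg$reference]]
    sm <- summarize_pi(prof, state$aln, structure = ref$structure,
                       groups = state$groups,
                       annotations = ref$annotations,
                       hotspot_threshold = p$pi$hotspot_threshold %||% 0.01)
    write_pi_bed(prof, out_file("pi_windows.bed"))
    outputs <<- c(outputs, out_file("pi_windows.bed"))
    if (!is.null(sm$by_region)) {
      write_tsv(sm$by_region, out_file("pi_by_region.tsv"))
      outputs <<- c(outputs, out_file("pi_by_region.tsv"))
    }
    if (!is.null(sm$by_group)) {
      write_tsv(sm$by_group, out_file("pi_by_group.tsv"))
      outputs <<- c(outputs, out_file("pi_by_group.tsv"))
    }
    summary$pi_total <<- prof$pi_total
  })

  run_stage("markers", "variants", function() {
    if (is.null(state$diagnostics)) stop("markers need a groups file")
    constraints <- marker_constraints(
      product_range = p$markers$product_range %||% c(100L, 300L),
      min_size_diff = p$markers$min_size_diff %||% 10L)
    dv <- state$diagnostics
    im <- design_indel_markers(state$aln, dv, state$groups, constraints,
                               variants = state$variants)
    write_tsv(im, out_file("indel_markers.tsv"))
    outputs <<- c(outputs, out_file("indel_markers.tsv"))
    summary$n_indel_markers <<- sum(im$status == "ok")
    snps <- which(dv$kind == "SNP")
    max_snps <- p$markers$max_snps %||% 50L
    if (length(snps) > max_snps) snps <- snps[seq_len(max_snps)]
    dlist <- list()
    for (i in snps) {
      d <- tryCatch(design_dcaps(state$aln, dv[i, , drop = FALSE],
                                 state$groups, constraints = constraints,
                                 variants = state$variants),
                    error = function(e) NULL)
      if (!is.null(d) && nrow(d)) dlist[[length(dlist) + 1L]] <- d
    }
    dc <- if (length(dlist)) do.call(rbind, dlist) else NULL
    if (!is.null(dc)) {
      dc$id <- sprintf("d%02d", seq_len(nrow(dc)))
      write_tsv(dc[, setdiff(names(dc), c("fragments", "group_allele"))],
                out_file("dcaps_markers.tsv"))
      outputs <<- c(outputs, out_file("dcaps_markers.tsv"))
    }
    summary$n_dcaps <<- if (is.null(dc)) 0L else nrow(dc)
  })

  run_stage("phylo", "align", function() {
    annotated <- all(vapply(state$genomes, function(g)
      !is.null(g$annotations) && nrow(g$annotations) > 0L, logical(1)))
    outg <- p$phylo$outgroup %||% NULL
    boot <- p$phylo$bootstrap_n %||% 1000L
    model <- p$phylo$model %||% "JC69"
    tree <- if (annotated) {
      sm <- build_supermatrix(extract_shared_genes(state$genomes))
      write_supermatrix(sm, out_file("supermatrix.fasta"),
                        out_file("partitions.txt"))
      outputs <<- c(outputs, out_file("supermatrix.fasta"),
                    out_file("partitions.txt"))
      nj_tree(sm, model, boot, seed = cfg$seed, outgroup = outg)
    } else {
      ## without per-taxon annotations fall back to the whole-genome
      ## alignment, which carries the same SNP signal
      nj_tree(state$aln$seqs, model, boot, seed = cfg$seed, outgroup = outg)
    }
    ape::write.tree(tree, out_file("tree.nwk"))
    outputs <<- c(outputs, out_file("tree.nwk"))
  })

  manifest <- list(stages = stages,
                   outputs = data.frame(
                     file = basename(outputs),
                     md5 = unname(tools::md5sum(outputs)),
                     stringsAsFactors = FALSE),
                   summary = summary,
                   seed = cfg$seed)
  jsonlite::write_json(manifest, out_file("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
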