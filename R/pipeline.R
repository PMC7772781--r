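#' Read and validate a pipeline configuration
#'
#' YAML (or JSON) configuration with `outdir`, `seed`, an `inputs` block
#' (paths for `genes`, `enhancers`, `expression`, `ernas`, `chrom_sizes`,
#' a named `peaks` map and an optional named `tracks` map) and an
#' optional `params` block overriding analysis defaults. Every referenced
#' input path must exist at validation time.
#'
#' @param path Path to a YAML/JSON config file, or an equivalent list.
#' @return Validated config list with defaults filled in.
#' @export
readPipelineConfig <- function(path) {
  config <- if (is.character(path)) yaml::read_yaml(path) else path
  if (is.null(config$outdir)) stop("config needs 'outdir'", call. = FALSE)
  if (is.null(config$seed)) config$seed <- 1L
  inp <- config$inputs
  if (is.null(inp)) stop("config needs an 'inputs' block", call. = FALSE)
  required <- c("genes", "enhancers", "expression", "ernas", "chrom_sizes")
  for (k in required) {
    if (is.null(inp[[k]])) {
      .stopf("config inputs block is missing '%s'", k)
    }
  }
  if (is.null(inp$peaks) || is.null(names(inp$peaks))) {
    stop("config inputs block needs a named 'peaks' map", call. = FALSE)
  }
  paths <- c(unlist(inp[required]), unlist(inp$peaks), unlist(inp$tracks))
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L) {
    .stopf("config validation error: input file(s) not found: %s",
           paste(missing, collapse = ", "))
  }
  defaults <- list(bin_width = 10L, assignment_window = 2000L,
                   genic_flank = 2000L, promoter_exclusion = 1000L,
                   association_max_distance = 1e5, expressed_tpm = 1.0,
                   tss_window_bp = 4000L, heatmap_window_bp = 2000L)
  config$params <- utils::modifyList(defaults,
                                     config$params %||% list())
  config
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order — input parsing, occupancy
#' calling and enhancer-state classification, positional statistics,
#' metagene profiles, density/knockdown enrichment, eRNA containment,
#' and expression integration — writing each stage's outputs plus a
#' manifest (`manifest.tsv`: file, stage, md5 checksum) into
#' `config$outdir`. Identical config and inputs give identical manifest
#' checksums. A stage failure aborts with the stage name; outputs
#' written up to that point are flagged partial in the manifest.
#'
#' @param config Path to a config file or a config list (see
#'   [readPipelineConfig()]).
#' @return The manifest data.frame, invisibly.
#' @export
runPipeline <- function(config) {
  config <- readPipelineConfig(config)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  prm <- config$params
  manifest <- data.frame(file = character(), stage = character(),
                         stringsAsFactors = FALSE)
  register <- function(file, stage) {
    manifest <<- rbind(manifest, data.frame(file = file, stage = stage,
                                            stringsAsFactors = FALSE))
  }
  writeManifest <- function(partial) {
    manifest$md5 <- unname(tools::md5sum(file.path(outdir,
                                                   manifest$file)))
    manifest$partial <- partial
    utils::write.table(manifest, file.path(outdir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest
  }
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      writeManifest(partial = TRUE)
      .stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  wjson <- function(x, file, stageName) {
    jsonlite::write_json(x, file.path(outdir, file), auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE)
    register(file, stageName)
  }
  wtsv <- function(df, file, stageName) {
    utils::write.table(df, file.path(outdir, file), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    register(file, stageName)
  }

  ## io
  io <- stage("io", {
    inp <- config$inputs
    cs <- utils::read.table(inp$chrom_sizes, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    sizes <- stats::setNames(cs$size, cs$chrom)
    peaks <- lapply(names(inp$peaks), function(f) {
      readNarrowPeak(inp$peaks[[f]], f)
    })
    names(peaks) <- names(inp$peaks)
    tracks <- lapply(inp$tracks %||% list(), function(p) {
      readBedGraph(p, prm$bin_width, genomeSizes = sizes)
    })
    list(genes = readGeneTable(inp$genes),
         enhancers = readEnhancerBed(inp$enhancers),
         expression = readExpressionTable(inp$expression),
         ernas = readBed(inp$ernas), peaks = peaks, tracks = tracks,
         sizes = sizes)
  })

  ## occupancy
  occ <- stage("occupancy", {
    m <- callOccupancy(io$enhancers, io$peaks)
    calls <- occupancyCalls(m)
    wtsv(data.frame(region_id = rownames(calls),
                    1L * calls, check.names = FALSE),
         "occupancy_matrix.tsv", "occupancy")
    if (all(c("H3K27ac", "H3K4me1") %in% colnames(calls))) {
      wtsv(classifyStates(m), "enhancer_states.tsv", "occupancy")
      vf <- intersect(c("H3K27ac", "H3K4me1", "Ctr9"), colnames(calls))
      wjson(as.list(vennCounts(m, vf)), "venn_counts.json", "occupancy")
    }
    if (all(c("H3K27ac", "Ctr9") %in% names(io$peaks))) {
      pred <- predictActiveEnhancers(io$peaks$H3K27ac, io$peaks$Ctr9,
                                     io$genes, prm$promoter_exclusion)
      writeBed(pred, file.path(outdir, "predicted_enhancers.bed"))
      register("predicted_enhancers.bed", "occupancy")
    }
    if ("Ctr9" %in% names(io$peaks)) {
      wtsv(annotatePeaks(io$peaks$Ctr9, io$genes, prm$genic_flank),
           "ctr9_peak_annotation.tsv", "occupancy")
    }
    m
  })

  ## positional
  pairs <- stage("positional", {
    offs <- do.call(rbind, lapply(
      intersect(c("NELFA", "Ser5p", "Ctr9"), names(io$peaks)),
      function(f) {
        s <- factorOffsetSummary(io$peaks[[f]], io$genes,
                                 prm$assignment_window)
        data.frame(factor = f, n = s$n, mean = s$mean, median = s$median,
                   q25 = s$q25, q75 = s$q75, stringsAsFactors = FALSE)
      }))
    wtsv(offs, "tss_offsets.tsv", "positional")
    pairs <- NULL
    if (all(c("NELFA", "Ctr9") %in% names(io$peaks))) {
      pairs <- pairNelfaCtr9(io$enhancers, io$peaks$NELFA, io$peaks$Ctr9)
      wtsv(pairs, "nelfa_ctr9_pairs.tsv", "positional")
    }
    pairs
  })

  ## metagene
  stage("metagene", {
    if (length(io$tracks) > 0L) {
      profs <- lapply(io$tracks, function(tr) {
        tssWindowProfile(toRPM(tr), io$genes, prm$tss_window_bp)
      })
      df <- data.frame(offset = as.numeric(names(profs[[1L]])),
                       do.call(cbind, profs), check.names = FALSE)
      wtsv(df, "tss_profiles.tsv", "metagene")
    }
    NULL
  })

  ## enrichment
  stage("enrichment", {
    if ("Ctr9" %in% names(io$tracks)) {
      dens <- regionDensity(toRPM(io$tracks$Ctr9), io$enhancers)
      wtsv(dens, "ctr9_density.tsv", "enrichment")
      ct <- compareClasses(dens, "SE", "TE")
      wjson(ct, "density_contrast.json", "enrichment")
    }
    if (all(c("Ser2p", "Ser2p_kd") %in% names(io$tracks))) {
      fc <- occupancyFoldChange(toRPM(io$tracks$Ser2p),
                                toRPM(io$tracks$Ser2p_kd), io$enhancers)
      wtsv(fc, "ser2p_fold_change.tsv", "enrichment")
    }
    shuf <- shuffleIntervals(io$enhancers, io$sizes, config$seed)
    writeBed(shuf, file.path(outdir, "shuffled_intervals.bed"))
    register("shuffled_intervals.bed", "enrichment")
    NULL
  })

  ## ernas
  stage("ernas", {
    calls <- occupancyCalls(occ)
    if (all(c("Ctr9", "Ser2p") %in% colnames(calls))) {
      er <- callErna(io$enhancers, io$ernas, occ)
      wtsv(er$calls, "erna_calls.tsv", "ernas")
      wjson(er$summary, "erna_summary.json", "ernas")
    }
    NULL
  })

  ## expression_integration
  stage("expression_integration", {
    expr <- io$expression
    expr$group <- associateGenes(io$genes, io$enhancers,
                                 prm$association_max_distance)[
      match(expr$gene_id, io$genes$gene_id)]
    expr <- filterExpressed(expr, prm$expressed_tpm)
    lfc <- log2FoldChange(expr)
    gc <- groupContrast(lfc, expr$group)
    wtsv(maPlotData(expr, prm$expressed_tpm), "ma_plot.tsv",
         "expression_integration")
    wjson(list(summary = gc$summary, pairwise = gc$pairwise),
          "expression_contrast.json", "expression_integration")
    NULL
  })

  invisible(writeManifest(partial = FALSE))
}
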