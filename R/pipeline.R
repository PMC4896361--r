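#' Pipeline configuration
#'
#' Either file inputs (`markerFile`, optional `traitFile`,
#' `intensityFile`) or a `simulate` block (a [simulationConfig()]) must be
#' given. The master `seed` is propagated to every stochastic stage with
#' fixed stage offsets, so any stage can be re-run in isolation and
#' reproduce the pipeline's output.
#'
#' @param markerFile,traitFile,intensityFile input paths (or `NULL`).
#' @param simulate a [simulationConfig()] (or `NULL`).
#' @param kRange contiguous K range for the admixture scan.
#' @param nReplicates replicate chains per K for delta-K.
#' @param burnIn,reps MCMC settings per chain.
#' @param nPerm permutations for AMOVA, Phi-st and the GLM/SA scans.
#' @param nBoot bootstrap resamples for Shannon diversity.
#' @param alpha1,alpha2 association significance thresholds.
#' @param seed master seed.
#' @param outDir output directory (`NULL` = no files written).
#' @param runAssociation run the trait-marker association stage (requires
#'   traits).
#' @return list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(markerFile = NULL, traitFile = NULL,
                           intensityFile = NULL, simulate = NULL,
                           kRange = 2:15, nReplicates = 5L,
                           burnIn = 50000L, reps = 100000L,
                           nPerm = 1000L, nBoot = 10000L,
                           alpha1 = 0.05, alpha2 = 0.01, seed = 1L,
                           outDir = NULL, runAssociation = TRUE) {
  if (is.null(markerFile) && is.null(simulate))
    stop("either markerFile or a simulate block is required")
  if (!is.null(markerFile) && !file.exists(markerFile))
    stop("marker file not found: ", markerFile)
  if (!is.null(traitFile) && !file.exists(traitFile))
    stop("trait file not found: ", traitFile)
  if (runAssociation && is.null(traitFile) && is.null(simulate))
    stop("association requested but no trait input is available")
  stopifnot(all(diff(kRange) == 1), nReplicates >= 1)
  structure(list(markerFile = markerFile, traitFile = traitFile,
                 intensityFile = intensityFile, simulate = simulate,
                 kRange = as.integer(kRange),
                 nReplicates = as.integer(nReplicates),
                 burnIn = as.integer(burnIn), reps = as.integer(reps),
                 nPerm = as.integer(nPerm), nBoot = as.integer(nBoot),
                 alpha1 = alpha1, alpha2 = alpha2, seed = as.integer(seed),
                 outDir = outDir, runAssociation = runAssociation),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the [pipelineConfig()] arguments; a `simulate`
#' mapping is passed to [simulationConfig()].
#'
#' @param path YAML file path.
#' @return a `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate)) y$simulate <- do.call(simulationConfig, y$simulate)
  if (!is.null(y$kRange) && length(y$kRange) == 2)
    y$kRange <- seq(y$kRange[1], y$kRange[2])
  do.call(pipelineConfig, y)
}

stageSeed <- function(config, offset) config$seed + offset

#' Run the full dominant-marker analysis pipeline
#'
#' Stages, mirroring the order of a typical diversity study: marker
#' summaries; Jaccard similarity / distance, PCoA, genotype NJ tree;
#' admixture scan over the K range with replicate chains, Evanno delta-K
#' and the best-K fit; hard population assignment and the population
#' divergence tree; AMOVA, pairwise Phi-st, Shannon diversity; trait-marker
#' association (MLM Q+K, permutation GLM and SA, rank-and-confirm); trait
#' summaries, rotated PCA and trait-profile clustering. A failure in any
#' stage aborts with the stage name; results computed so far are returned
#' in the error's `partial` attribute. With `outDir` set, tables, trees
#' and a run manifest are written.
#'
#' @param config a [pipelineConfig()].
#' @return list of class `PipelineResult` with one element per stage plus
#'   `manifest`.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  res <- list()
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      err <- simpleError(paste0("pipeline stage '", name, "' failed: ",
                                conditionMessage(e)))
      attr(err, "partial") <- res
      stop(err)
    })
  }

  res$inputs <- stage("inputs", {
    if (!is.null(config$simulate)) {
      cfg <- config$simulate
      cfg$seed <- stageSeed(config, 11L)
      sim <- simulateMarkers(cfg)
      tr <- simulateTraits(sim, cfg)
      list(markers = sim$markers, traits = tr$traits, truth = sim$truth,
           causal = tr$causal)
    } else {
      markers <- readMarkerMatrix(config$markerFile)
      if (!is.null(config$intensityFile)) {
        inten <- readIntensityMatrix(config$intensityFile)
        markers <- DartSet(bandCalls(markers),
                           intensity = inten[genotypeIds(markers),
                                             markerIds(markers)])
      }
      traits <- if (!is.null(config$traitFile))
        readTraitTable(config$traitFile) else NULL
      if (!is.null(traits)) {
        al <- alignGenotypes(markers, traits)
        markers <- al$markers; traits <- al$traits
      }
      list(markers = markers, traits = traits)
    }
  })
  markers <- res$inputs$markers

  res$markerStats <- stage("markerStats", markerSummaries(markers))

  res$distance <- stage("distance", {
    s <- jaccardSimilarity(markers)
    d <- distanceTransform(s)
    list(similarity = s, distance = d, pcoa = pcoa(d),
         njTree = njTree(d))
  })

  res$admixture <- stage("admixture", {
    fits <- list()
    for (K in config$kRange)
      for (r in seq_len(config$nReplicates))
        fits[[length(fits) + 1]] <-
          fitAdmixture(markers, K, burnIn = config$burnIn,
                       reps = config$reps,
                       seed = stageSeed(config, 100L + 1000L * K + r))
    dk <- deltaK(fits)
    kBest <- bestK(dk)
    if (is.na(kBest)) kBest <- config$kRange[1]
    best <- fitAdmixture(markers, kBest, burnIn = config$burnIn,
                         reps = config$reps,
                         seed = stageSeed(config, 77L))
    list(deltaK = dk, bestK = kBest, fit = best,
         divergence = clusterDivergence(best),
         populationTree = if (kBest >= 2)
           njTree(clusterDivergence(best)) else NULL)
  })
  pops <- hardAssignment(res$admixture$fit)

  res$diversity <- stage("diversity", {
    d <- res$distance$distance
    if (length(unique(pops)) >= 2)
      list(pops = pops,
           amova = amova(d, pops, nPerm = config$nPerm,
                         seed = stageSeed(config, 201L)),
           phiSt = pairwisePhiSt(d, pops, nPerm = config$nPerm,
                                 seed = stageSeed(config, 202L)),
           shannon = shannonDiversity(markers, pops, nBoot = config$nBoot,
                                      seed = stageSeed(config, 203L)))
    else list(pops = pops, amova = NULL, phiSt = NULL,
              shannon = NULL)
  })

  if (config$runAssociation && !is.null(res$inputs$traits)) {
    res$association <- stage("association", {
      traits <- res$inputs$traits
      Q <- admixQ(res$admixture$fit)
      Kr <- kinship(markers)
      mlm <- mlmScan(traits, markers, Q = Q, Kr = Kr)
      set.seed(stageSeed(config, 301L))
      glm <- glmPermScan(traits, markers, covariates = Q,
                         nPerm = config$nPerm)
      set.seed(stageSeed(config, 302L))
      sa <- glmPermScan(traits, markers, covariates = pops,
                        nPerm = config$nPerm)
      list(kinship = Kr, mlm = mlm, glm = glm, sa = sa,
           table = rankAndConfirm(mlm, glm, sa, config$alpha1,
                                  config$alpha2))
    })
    res$phenotype <- stage("phenotype", {
      traits <- res$inputs$traits
      list(summaries = traitSummaries(traits, alpha = config$alpha1),
           pca = rotatedPca(traits),
           clusters = genotypeClusters(traits))
    })
  }

  res$manifest <- list(
    package = as.character(utils::packageVersion("dartmix")),
    seed = config$seed,
    kRange = config$kRange, nReplicates = config$nReplicates,
    burnIn = config$burnIn, reps = config$reps, nPerm = config$nPerm,
    nBoot = config$nBoot, bestK = res$admixture$bestK,
    wallClockSec = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  if (!is.null(config$outDir)) writePipelineOutputs(res, config)
  class(res) <- "PipelineResult"
  res
}

writePipelineOutputs <- function(res, config) {
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outDir, f)
  wt <- function(x, f) write.table(x, out(f), sep = "\t", quote = FALSE,
                                   row.names = FALSE)
  wt(res$markerStats, "marker_summaries.tsv")
  writeSquareMatrix(res$distance$distance, out("jaccard_distance.phy"))
  wt(data.frame(id = rownames(res$distance$pcoa$coordinates),
                res$distance$pcoa$coordinates), "pcoa_coordinates.tsv")
  writeNewick(res$distance$njTree, out("genotype_nj.nwk"))
  wt(res$admixture$deltaK, "delta_k.tsv")
  Q <- admixQ(res$admixture$fit)
  wt(data.frame(id = rownames(Q), Q), "q_matrix.tsv")
  if (!is.null(res$admixture$populationTree))
    writeNewick(res$admixture$populationTree, out("population_nj.nwk"))
  if (!is.null(res$diversity$amova)) {
    a <- res$diversity$amova
    wt(data.frame(source = c("Among populations", "Within populations"),
                  df = c(a$dfAmong, a$dfWithin),
                  variance = c(a$Va, a$Vb),
                  percent = c(a$percentAmong, a$percentWithin),
                  p = c(a$pAmong, NA)), "amova.tsv")
    wt(data.frame(population = rownames(res$diversity$phiSt$phiST),
                  res$diversity$phiSt$phiST), "phist.tsv")
    wt(res$diversity$shannon, "shannon.tsv")
  }
  if (!is.null(res$association))
    wt(res$association$table, "associations.tsv")
  if (!is.null(res$phenotype)) {
    wt(res$phenotype$summaries, "trait_summaries.tsv")
    if (res$phenotype$pca$nRetained > 0)
      wt(data.frame(trait = rownames(res$phenotype$pca$rotatedLoadings),
                    res$phenotype$pca$rotatedLoadings,
                    component = res$phenotype$pca$assignment),
         "trait_pca_loadings.tsv")
  }
  yaml::write_yaml(res$manifest, file.path(config$outDir, "manifest.yaml"))
  invisible(NULL)
}
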