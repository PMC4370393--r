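#' @include admixture.R
NULL

#' Read and validate a pipeline run configuration
#'
#' The YAML config holds the input matrix path (or \code{simulate: true} for
#' a synthetic study-shaped dataset), an output directory, a global seed and
#' a \code{stages} map of per-stage toggles and parameters. Referenced paths
#' are checked here, before any stage runs.
#'
#' @param path YAML file.
#' @return validated config list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  cfg <- yaml::read_yaml(path)
  validateRunConfig(cfg)
}

validateRunConfig <- function(cfg) {
  if (is.null(cfg$seed)) stop("config needs a global 'seed'")
  if (is.null(cfg$outdir)) stop("config needs an 'outdir'")
  if (is.null(cfg$stages)) cfg$stages <- list()
  if (!is.null(cfg$input) && !file.exists(cfg$input))
    stop("input path does not exist: ", cfg$input)
  if (!is.null(cfg$sites) && !file.exists(cfg$sites))
    stop("sites path does not exist: ", cfg$sites)
  if (is.null(cfg$input) && !isTRUE(cfg$simulate))
    stop("config needs either 'input' or 'simulate: true'")
  st <- cfg$stages$structure
  if (is.list(st) && !is.null(st$k_range) &&
      any(diff(unlist(st$k_range)) <= 0))
    stop("structure k_range must be increasing")
  cfg
}

stageSeed <- function(seed, stage) {
  # deterministic per-stage seeds derived from the global one
  offs <- c(simulate = 1L, informativeness = 2L, diversity = 3L, amova = 4L,
            pairwise_fst = 5L, geneflow = 6L, ld = 7L, nei_distance = 8L,
            upgma = 9L, pcoa = 10L, mantel = 11L, hickory = 12L,
            structure = 13L)
  as.integer(seed) + 1000L * offs[[stage]]
}

writeTSV <- function(df, path, stage, seed, params = "") {
  hdr <- c(sprintf("# dompop %s",
                   as.character(utils::packageVersion("dompop"))),
           sprintf("# stage=%s seed=%d %s", stage, seed, params))
  con <- file(path, "w")
  writeLines(hdr, con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = TRUE))
  close(con)
  path
}

stageOn <- function(cfg, stage, default = TRUE) {
  s <- cfg$stages[[stage]]
  if (is.null(s)) return(default)
  if (is.logical(s)) return(isTRUE(s))
  !isFALSE(s$enabled)
}

stagePar <- function(cfg, stage, name, default) {
  v <- cfg$stages[[stage]][[name]]
  if (is.null(v)) default else v
}

#' Run the full dominant-marker analysis pipeline
#'
#' Executes the enabled stages in dependency order — marker informativeness,
#' within-population diversity, AMOVA, pairwise Fst, gene flow, LD screen,
#' Nei distance with UPGMA and PCoA, Mantel isolation-by-distance, the
#' Bayesian hierarchical fits, and admixture clustering with Evanno's
#' delta-K — writing each table as TSV with a provenance header (package
#' version, stage seed, parameters). Every stage draws its seed
#' deterministically from the global one, so disabling a stage never
#' changes another stage's numbers and a rerun with the same config is
#' byte-identical.
#'
#' @param config a config list or path to a YAML file
#'   (see \code{\link{readRunConfig}}).
#' @return invisibly, a named list of the objects computed per stage.
#' @export
runPipeline <- function(config) {
  cfg <- if (is.character(config)) readRunConfig(config)
         else validateRunConfig(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  log <- file.path(cfg$outdir, "pipeline.log")
  cat(sprintf("dompop pipeline; global seed %d\n", cfg$seed), file = log)
  note <- function(...) cat(sprintf(...), file = log, append = TRUE)
  out <- list()
  t0 <- proc.time()[["elapsed"]]
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    note("stage %s done at %.2fs\n", stage, t1 - t0)
  }
  run <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e)))
  }

  if (!is.null(cfg$input)) {
    m <- run("input", readBandMatrix(cfg$input,
                                     dialect = stagePar(cfg, "simulate",
                                                        "dialect", "csv")))
  } else {
    sim <- run("simulate", studyLikeDataset(stageSeed(cfg$seed, "simulate")))
    m <- sim$matrix
    out$truth <- sim$truth
    writeBandMatrix(m, file.path(cfg$outdir, "simulated_matrix.csv"))
  }
  out$matrix <- m
  tick("input")

  if (stageOn(cfg, "informativeness") && !is.null(primerOf(m))) {
    out$informativeness <- run("informativeness", primerReport(m))
    writeTSV(out$informativeness,
             file.path(cfg$outdir, "informativeness.tsv"),
             "informativeness", cfg$seed)
    tick("informativeness")
  }
  if (stageOn(cfg, "diversity")) {
    out$diversity <- run("diversity", populationDiversity(m))
    writeTSV(out$diversity, file.path(cfg$outdir, "diversity.tsv"),
             "diversity", cfg$seed)
    tick("diversity")
  }
  if (stageOn(cfg, "amova")) {
    sd <- stageSeed(cfg$seed, "amova")
    np <- stagePar(cfg, "amova", "n_perm", 1000L)
    out$amova <- run("amova", amova(m, n_perm = np, seed = sd))
    writeTSV(amovaTable(out$amova), file.path(cfg$outdir, "amova.tsv"),
             "amova", sd, sprintf("n_perm=%d phiST=%.6f p=%.4f", np,
                                  phiST(out$amova), amovaPValue(out$amova)))
    tick("amova")
  }
  if (stageOn(cfg, "pairwise_fst")) {
    sd <- stageSeed(cfg$seed, "pairwise_fst")
    out$pairwise_fst <- run("pairwise_fst",
                            pairwiseFst(m, n_perm = stagePar(
                              cfg, "pairwise_fst", "n_perm", 0L), seed = sd))
    writeTSV(as.data.frame(distValues(out$pairwise_fst$fst)),
             file.path(cfg$outdir, "pairwise_fst.tsv"), "pairwise_fst", sd)
    tick("pairwise_fst")
  }
  if (stageOn(cfg, "geneflow")) {
    fst <- phiST(run("geneflow", amova(m, n_perm = 0L)))
    out$geneflow <- geneFlow(fst)
    writeTSV(data.frame(fst = fst, Nm = out$geneflow),
             file.path(cfg$outdir, "geneflow.tsv"), "geneflow", cfg$seed)
    tick("geneflow")
  }
  if (stageOn(cfg, "ld", default = FALSE)) {
    out$ld <- run("ld", ldScreen(m, alpha = stagePar(cfg, "ld", "alpha",
                                                     0.05)))
    writeTSV(as.data.frame(out$ld), file.path(cfg$outdir, "ld.tsv"),
             "ld", cfg$seed)
    tick("ld")
  }
  if (stageOn(cfg, "nei_distance")) {
    out$nei <- run("nei_distance", neiDistance(m))
    writeTSV(as.data.frame(distValues(out$nei)),
             file.path(cfg$outdir, "nei_distance.tsv"), "nei_distance",
             cfg$seed)
    tick("nei_distance")
  }
  if (stageOn(cfg, "upgma")) {
    d <- if (!is.null(out$nei)) out$nei else neiDistance(m)
    out$upgma <- run("upgma", upgma(d))
    writeLines(newick(out$upgma), file.path(cfg$outdir, "upgma.nwk"))
    tick("upgma")
  }
  if (stageOn(cfg, "pcoa")) {
    d <- if (!is.null(out$nei)) out$nei else neiDistance(m)
    out$pcoa <- run("pcoa", pcoa(d))
    writeTSV(data.frame(item = rownames(out$pcoa$coordinates),
                        out$pcoa$coordinates,
                        check.names = FALSE),
             file.path(cfg$outdir, "pcoa.tsv"), "pcoa", cfg$seed,
             sprintf("percent=%s",
                     paste(round(out$pcoa$percent, 2), collapse = ",")))
    tick("pcoa")
  }
  if (stageOn(cfg, "mantel", default = FALSE) && !is.null(cfg$sites)) {
    sites <- read.table(cfg$sites, sep = ",", header = TRUE,
                        stringsAsFactors = FALSE)
    geo <- geographicDistance(sites)
    gen <- if (!is.null(out$nei)) out$nei else neiDistance(m)
    ord <- match(labels(geo), labels(gen))
    gen <- LabeledDistance(distValues(gen)[ord, ord], units = distUnits(gen))
    out$mantel <- run("mantel", mantelTest(
      gen, geo, n_perm = stagePar(cfg, "mantel", "n_perm", 999L),
      seed = stageSeed(cfg$seed, "mantel")))
    writeTSV(data.frame(r = out$mantel$r, p = out$mantel$p,
                        n_perm = out$mantel$n_perm),
             file.path(cfg$outdir, "mantel.tsv"), "mantel",
             stageSeed(cfg$seed, "mantel"))
    tick("mantel")
  }
  if (stageOn(cfg, "hickory", default = FALSE)) {
    sd <- stageSeed(cfg$seed, "hickory")
    variants <- unlist(stagePar(cfg, "hickory", "variants",
                                list("full", "f0")))
    fits <- lapply(variants, function(v)
      run("hickory", fitHickory(
        m, variant = v,
        burn_in = stagePar(cfg, "hickory", "burn_in", 50000L),
        samples = stagePar(cfg, "hickory", "samples", 250000L),
        thin = stagePar(cfg, "hickory", "thin", 50L), seed = sd)))
    names(fits) <- variants
    out$hickory <- fits
    smry <- do.call(rbind, lapply(fits, function(f)
      cbind(variant = f@variant, f@summary, DIC = f@dic)))
    writeTSV(smry, file.path(cfg$outdir, "hickory.tsv"), "hickory", sd)
    writeTSV(compareModels(fits), file.path(cfg$outdir, "hickory_dic.tsv"),
             "hickory", sd)
    tick("hickory")
  }
  if (stageOn(cfg, "structure", default = FALSE)) {
    sd <- stageSeed(cfg$seed, "structure")
    kr <- unlist(stagePar(cfg, "structure", "k_range", list(1L, 4L)))
    nrep <- stagePar(cfg, "structure", "n_replicates", 3L)
    bi <- stagePar(cfg, "structure", "burn_in", 10000L)
    rp <- stagePar(cfg, "structure", "reps", 100000L)
    runs <- list()
    for (K in seq(kr[1L], kr[2L])) {
      rs <- fitAdmixture(m, K = K, burn_in = bi, reps = rp,
                         seed = sd + 37L * K, n_replicates = nrep)
      if (nrep == 1L) rs <- list(rs)
      runs[[as.character(K)]] <- rs
    }
    tab <- do.call(rbind, lapply(names(runs), function(k)
      data.frame(K = as.integer(k),
                 lnP = vapply(runs[[k]], lnProbData, 0))))
    ev <- run("structure", evannoDeltaK(tab))
    out$structure <- list(runs = runs, evanno = ev)
    writeTSV(deltaKTable(ev), file.path(cfg$outdir, "evanno.tsv"),
             "structure", sd, sprintf("optimalK=%d", optimalK(ev)))
    bestQ <- ancestryQ(runs[[as.character(optimalK(ev))]][[1L]])
    writeTSV(data.frame(id = rownames(bestQ), pop = unname(populations(m)),
                        bestQ, check.names = FALSE),
             file.path(cfg$outdir, "ancestry_Q.tsv"), "structure", sd)
    tick("structure")
  }
  invisible(out)
}
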