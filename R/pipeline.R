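## End-to-end orchestration: counting -> diversity/dispersion/indicators ->
## topics -> feature networks + ERGM -> co-citation clustering, with all
## intermediate tables written to disk and a machine-readable report.

#' Default pipeline configuration
#'
#' One master seed fans out to per-stage seeds by fixed offsets so stages
#' are reproducible when run standalone.
#'
#' @param seed master seed.
#' @return named list of pipeline settings.
#' @export
pipelineConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    nPerm = 999L,          # indicator-analysis permutations
    kTopics = 20L,         # topic count (reference analysis uses 100)
    topicsIters = 150L,
    topicsBurnin = 75L,
    hdiMass = 0.99,
    topN = 100L,           # co-citation subnetwork size
    tau = 1,               # article-tie binarization threshold
    robustnessN = c(60L, 80L, 100L),
    focalGroup = "complexity")
}

stageSeed <- function(cfg, offset) cfg$seed + offset

runStage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full research-weaving analysis
#'
#' Executes the pipeline on a corpus and writes every intermediate table
#' plus a JSON report to `outDir`. Fully deterministic given the config
#' seed. Stages may be restricted (e.g. to skip the topic model); the
#' report only contains sections for the stages run.
#'
#' @param corpus a [Corpus-class] (e.g. from [readCorpus()] or
#'   [simulateCorpus()]).
#' @param outDir output directory.
#' @param config list from [pipelineConfig()]; fields may be overridden.
#' @param lexicon a [FeatureLexicon-class].
#' @param stages subset of c("diversity", "indval", "topics", "featnet",
#'   "cocite"); counting always runs.
#' @return the report, invisibly (also written to `outDir/report.json`).
#' @export
runAll <- function(corpus, outDir, config = pipelineConfig(),
                   lexicon = defaultLexicon(),
                   stages = c("diversity", "indval", "topics", "featnet",
                              "cocite")) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = config$seed,
                 package_version = as.character(utils::packageVersion("ecoweave")))

  fm <- runStage("count", {
    fm <- buildFeatureMatrix(corpus, lexicon)
    fm <- suppressMessages(dropFeatureless(fm))
    relativeFrequency(fm)
  })
  writeFeatureTables(fm, outDir)
  grp <- as.character(fm$group)
  report$group_sizes <- as.list(table(grp))
  rf <- t(relFreq(fm))

  if ("diversity" %in% stages) {
    div <- runStage("diversity", {
      prof <- diversityProfile(rf)
      prof$group <- grp
      aR <- anovaCompare(prof$richness, grp)
      aH <- anovaCompare(prof$hill1, grp)
      bc <- brayCurtis(rf)
      disp <- dispersionTest(bc, grp)
      list(profile = prof, anovaRichness = aR, anovaHill1 = aH, disp = disp)
    })
    write.table(div$profile, file.path(outDir, "diversity.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(article_id = names(div$disp$distances),
                           group = grp,
                           distance = unname(div$disp$distances)),
                file.path(outDir, "dispersion.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    report$diversity <- list(
      mean_richness = lapply(split(div$profile$richness, grp), mean),
      mean_hill1 = lapply(split(div$profile$hill1, grp), mean),
      anova_richness = div$anovaRichness,
      anova_hill1 = div$anovaHill1)
    report$dispersion <- list(
      group_mean_distance = as.list(div$disp$groupMeans),
      group_sd_distance = as.list(div$disp$groupSds),
      F = div$disp$F, df1 = div$disp$df1, df2 = div$disp$df2,
      p = div$disp$p)
  }

  if ("indval" %in% stages) {
    iv <- runStage("indval", {
      ab <- indval(rf, grp, mode = "abundance", nPerm = config$nPerm,
                   seed = stageSeed(config, 1L))
      pr <- indval(rf, grp, mode = "presence", nPerm = config$nPerm,
                   seed = stageSeed(config, 1L))
      ab$p_holm <- p.adjust(ab$p, "holm")
      pr$p_holm <- p.adjust(pr$p, "holm")
      list(abundance = ab, presence = pr)
    })
    write.table(iv$abundance, file.path(outDir, "indval.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    report$indval <- list(
      n_significant_abundance = sum(iv$abundance$p < 0.05, na.rm = TRUE),
      n_significant_presence = sum(iv$presence$p < 0.05, na.rm = TRUE),
      n_significant_abundance_holm =
        sum(iv$abundance$p_holm < 0.05, na.rm = TRUE))
  }

  if ("topics" %in% stages) {
    tp <- runStage("topics", {
      ids <- colnames(fm)
      docs <- lapply(ids, function(id)
        preprocessForTopics(tokenize(articleText(corpus, id))))
      names(docs) <- ids
      tm <- fitTopics(docs, K = config$kTopics,
                      seed = stageSeed(config, 2L),
                      iters = config$topicsIters,
                      burnin = config$topicsBurnin)
      sel <- selectTopWords(tm, hdiMass = config$hdiMass)
      cmpT <- compareFeatureTopics(tm, sel, lexicon, grp)
      list(tm = tm, sel = sel, cmp = cmpT)
    })
    write.table(tp$sel$selection, file.path(outDir, "topics_beta.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(tp$cmp, file.path(outDir, "topic_feature_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    wide <- split(tp$cmp$meanDocProb, tp$cmp$group)
    report$topics <- list(
      K = tp$tm@K,
      vocabulary_size = length(tp$tm@vocabulary),
      mean_feature_doc_prob = lapply(wide, mean))
  }

  if ("featnet" %in% stages) {
    fn <- runStage("featnet", {
      b <- buildBipartite(fm)
      gf <- projectGraph(b, "feature", "count")
      ga <- projectGraph(b, "article", "count")
      nsf <- networkSummary(gf)
      gbin <- binarizeProjection(ga, tau = config$tau)
      erg <- ergmFit(gbin, focalGroup = config$focalGroup)
      list(b = b, gf = gf, ga = ga, nsf = nsf, erg = erg)
    })
    igraph::write_graph(fn$gf, file.path(outDir, "feature_projection.graphml"),
                        format = "graphml")
    write.table(igraph::as_data_frame(fn$gf),
                file.path(outDir, "feature_projection_edges.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(fn$erg$coefficients, file.path(outDir, "ergm.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    report$feature_network <- list(
      connectance = fn$nsf$connectance,
      S = fn$nsf$S, L = fn$nsf$L,
      top_strength = as.list(sort(fn$nsf$strength, decreasing = TRUE)[1:3]),
      ergm = split(fn$erg$coefficients[, c("estimate", "se", "z", "p")],
                   fn$erg$coefficients$term),
      ergm_converged = fn$erg$converged)
  }

  if ("cocite" %in% stages) {
    cc <- runStage("cocite", {
      g <- buildCocitation(corpus, group = config$focalGroup)
      # keep ids that survived the featureless exclusion out of scope here:
      # co-citation uses reference lists, not texts
      gTop <- topNSubgraph(g, config$topN)
      cl <- louvainCluster(gTop, seed = stageSeed(config, 3L))
      rb <- robustnessSweep(g, config$robustnessN,
                            seed = stageSeed(config, 4L))
      list(g = g, gTop = gTop, cl = cl, rb = rb)
    })
    igraph::write_graph(cc$gTop, file.path(outDir, "cocitation.graphml"),
                        format = "graphml")
    write.table(data.frame(
        node = names(cc$cl$membership),
        community = as.integer(cc$cl$membership),
        strength = igraph::strength(cc$gTop,
                                    weights = igraph::E(cc$gTop)$weight)),
      file.path(outDir, "clusters.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(cc$rb$ari))
      write.table(cc$rb$ari, file.path(outDir, "robustness.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    report$cocitation <- list(
      n_references = igraph::vcount(cc$g),
      n_communities = cc$cl$nCommunities,
      modularity = cc$cl$Q,
      community_sizes = as.list(table(as.integer(cc$cl$membership))),
      robustness_ari = if (is.null(cc$rb$ari)) NULL else cc$rb$ari$ari)
  }

  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
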