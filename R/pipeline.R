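# End-to-end orchestration: corpus -> rules -> graph/GCN/clusters ->
# differential -> consensus, with one JSON report and optional per-stage
# artifacts. Every stage failure is rethrown with the stage name so a
# pipeline abort always names its cause.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Pipeline configuration
#'
#' Collects every input, threshold, hyperparameter and seed of
#' \code{\link{runPipeline}} in one validated list. Either both corpus
#' paths or a \code{\link{syntheticConfig}} must be supplied. Defaults
#' mirror the package's reference analysis settings: Apriori at support
#' 0.08 / confidence 0.80 with single-herb consequents; a 32/16 GCN trained
#' 200 epochs at learning rate 0.01; silhouette-selected K over 2--10;
#' 1000-tree random forest at seed 123; rule arm pooled over the top 10
#' rules and cluster arm over the top cluster.
#'
#' @param corpus_anti,corpus_general Paths to long/wide corpus files (see
#'   \code{\link{readCorpus}}), or \linkS4class{PrescriptionCorpus} objects.
#' @param synthetic A \code{\link{syntheticConfig}} to generate both groups
#'   instead of reading files.
#' @param corpus_format \code{"long"} or \code{"wide"} for file input.
#' @param lexicon Optional path to a lexicon CSV or a
#'   \linkS4class{HerbLexicon}; applied to both corpora.
#' @param min_support,min_confidence,rhs_size Apriori thresholds.
#' @param hidden_dim,out_dim,epochs,learning_rate,negatives_per_edge GCN
#'   hyperparameters.
#' @param k \code{"auto"} or a fixed integer.
#' @param k_range Candidate K values when \code{k = "auto"}.
#' @param rf_trees,rf_seed Random-forest settings.
#' @param top_n_rules,n_clusters,rf_top_n Consensus selection widths.
#' @param seed Master seed for corpus generation, embedding and clustering.
#' @return A list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(corpus_anti = NULL, corpus_general = NULL,
                           synthetic = NULL, corpus_format = "long",
                           lexicon = NULL,
                           min_support = 0.08, min_confidence = 0.80,
                           rhs_size = 1L,
                           hidden_dim = 32L, out_dim = 16L, epochs = 200L,
                           learning_rate = 0.01, negatives_per_edge = 1L,
                           k = "auto", k_range = 2:10,
                           rf_trees = 1000L, rf_seed = 123L,
                           top_n_rules = 10L, n_clusters = 1L,
                           rf_top_n = 14L, seed = 1L) {
  if (is.null(synthetic) &&
      (is.null(corpus_anti) || is.null(corpus_general)))
    stop("either a synthetic config or both corpus inputs are required")
  cfg <- as.list(environment())
  class(cfg) <- "PipelineConfig"
  cfg
}

.loadGroupCorpus <- function(input, format, group) {
  if (is(input, "PrescriptionCorpus")) return(input)
  if (!is.character(input) || !file.exists(input))
    stop("corpus input for group '", group, "' not found: ", input)
  corp <- readCorpus(input, format = format)
  keep <- groupLabels(corp) == group
  if (!any(keep))
    stop("file ", input, " contains no '", group, "' prescriptions")
  subsetByGroup(corp, group)
}

#' Run the full core-herb mining pipeline
#'
#' Executes, in order: corpus loading or synthesis (with optional name
#' standardization); Apriori rule mining on the anti-recurrence corpus;
#' co-occurrence graph construction, GCN embedding, silhouette-selected
#' K-means and composite cluster scoring; two-group frequency and
#' random-forest differentials; and consensus extraction. The same
#' configuration (seeds included) always yields an identical report.
#'
#' @param config A \code{\link{pipelineConfig}}.
#' @param outDir Optional directory; when given, per-stage artifacts (rules
#'   and itemsets CSV, graph TSV, embedding TSV, cluster scores CSV,
#'   differential CSV, importance CSV) and the JSON report
#'   (\code{report.json}) are written there.
#' @return List with the fitted objects (\code{corpusAnti},
#'   \code{corpusGeneral}, \code{itemsets}, \code{rules}, \code{graph},
#'   \code{embedding}, \code{assignment}, \code{clusterScores},
#'   \code{differential}, \code{forest}, \code{consensus}) and
#'   \code{report}, the JSON-serializable summary.
#' @export
runPipeline <- function(config, outDir = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  c2 <- config

  if (!is.null(c2$synthetic)) {
    sim <- .stage("corpus", generateTwoGroupCorpus(c2$synthetic))
    full <- sim$corpus
    corpusAnti <- subsetByGroup(full, "anti_recurrence")
    corpusGeneral <- subsetByGroup(full, "general")
    truth <- sim$truth
  } else {
    corpusAnti <- .stage("corpus",
      .loadGroupCorpus(c2$corpus_anti, c2$corpus_format, "anti_recurrence"))
    corpusGeneral <- .stage("corpus",
      .loadGroupCorpus(c2$corpus_general, c2$corpus_format, "general"))
    truth <- NULL
  }
  if (!is.null(c2$lexicon)) {
    lex <- if (is(c2$lexicon, "HerbLexicon")) c2$lexicon
           else .stage("lexicon", readLexicon(c2$lexicon))
    corpusAnti <- .stage("lexicon", standardizeHerbs(corpusAnti, lex))
    corpusGeneral <- .stage("lexicon", standardizeHerbs(corpusGeneral, lex))
  }

  mat <- .stage("encode", binaryMatrix(corpusAnti))
  itemsets <- .stage("apriori",
    frequentItemsets(mat, c2$min_support))
  rules <- .stage("apriori",
    deriveRules(itemsets, mat, c2$min_confidence, c2$rhs_size))

  graph <- .stage("graph", buildCooccurrenceGraph(corpusAnti))
  embedding <- .stage("gcn",
    gcnEmbed(graph, hiddenDim = c2$hidden_dim, outDim = c2$out_dim,
             epochs = c2$epochs, learningRate = c2$learning_rate,
             negativesPerEdge = c2$negatives_per_edge, seed = c2$seed))
  assignment <- .stage("cluster",
    clusterEmbeddings(embedding, k = c2$k, kRange = c2$k_range,
                      seed = c2$seed))
  clusterScores <- .stage("cluster",
    scoreClusters(graph, corpusAnti, assignment))

  differential <- .stage("differential",
    frequencyDifferential(corpusAnti, corpusGeneral))
  forest <- .stage("differential",
    rfDifferential(corpusAnti, corpusGeneral, nTrees = c2$rf_trees,
                   seed = c2$rf_seed))

  ruleHerbs <- .stage("consensus", selectRuleHerbs(rules, c2$top_n_rules))
  clusterHerbs <- .stage("consensus",
    selectClusterHerbs(clusterScores, c2$n_clusters))
  consensus <- .stage("consensus",
    consensusCore(ruleHerbs, clusterHerbs, differential, forest,
                  rfTopN = c2$rf_top_n))

  topRule <- if (nrow(rules)) as.list(rules[1L, ]) else NULL
  report <- list(
    settings = list(
      min_support = c2$min_support, min_confidence = c2$min_confidence,
      rhs_size = c2$rhs_size, hidden_dim = c2$hidden_dim,
      out_dim = c2$out_dim, epochs = c2$epochs,
      learning_rate = c2$learning_rate, k = c2$k,
      rf_trees = c2$rf_trees, rf_seed = c2$rf_seed,
      top_n_rules = c2$top_n_rules, n_clusters = c2$n_clusters,
      seed = c2$seed),
    corpus = list(
      n_anti = nPrescriptions(corpusAnti),
      n_general = nPrescriptions(corpusGeneral),
      n_herbs_anti = length(vocabulary(corpusAnti)),
      n_herbs_general = length(vocabulary(corpusGeneral))),
    rules = list(n_itemsets = nrow(itemsets), n_rules = nrow(rules),
                 top_rule = topRule),
    gcn = list(final_loss = embedding@lossTrace[length(embedding@lossTrace)],
               k_selected = assignment@k,
               silhouette = assignment@silhouette),
    top_cluster = as.list(clusterScores[1L, ]),
    differential = list(
      n_high = sum(differential$band == "high"),
      n_moderate = sum(differential$band == "moderate"),
      n_slight = sum(differential$band == "slight")),
    forest = list(oob_error = forest$oob_error,
                  top_herbs = utils::head(forest$ranking, c2$rf_top_n)),
    consensus = list(
      rule_herbs = consensus@ruleHerbs,
      cluster_herbs = consensus@clusterHerbs,
      intersection = consensus@intersection,
      venn = as.list(consensus@vennCounts)))
  if (!is.null(truth))
    report$truth = list(
      planted_modules = truth$planted_modules,
      recovered_in_intersection = vapply(
        truth$planted_modules,
        function(m) length(intersect(m, consensus@intersection)), 0L))

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeRules(itemsets, file.path(outDir, "itemsets.csv"))
    writeRules(rules, file.path(outDir, "rules.csv"))
    writeGraph(graph, file.path(outDir, "graph_edges.tsv"))
    writeEmbedding(embedding, file.path(outDir, "embedding.tsv"))
    utils::write.csv(clusterScores, file.path(outDir, "cluster_scores.csv"),
                     row.names = FALSE)
    utils::write.csv(differential, file.path(outDir, "differential.csv"),
                     row.names = FALSE)
    utils::write.csv(forest$importance, file.path(outDir, "importance.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(corpusAnti = corpusAnti, corpusGeneral = corpusGeneral,
       itemsets = itemsets, rules = rules, graph = graph,
       embedding = embedding, assignment = assignment,
       clusterScores = clusterScores, differential = differential,
       forest = forest, consensus = consensus, report = report)
}

#' Read a pipeline configuration from YAML
#'
#' Maps a flat YAML document onto \code{\link{pipelineConfig}} arguments; a
#' \code{synthetic:} block, when present, is passed through
#' \code{\link{syntheticConfig}}.
#'
#' @param path YAML file path.
#' @return A \code{\link{pipelineConfig}}.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  if (!is.null(y$synthetic))
    y$synthetic <- do.call(syntheticConfig, y$synthetic)
  known <- names(formals(pipelineConfig))
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(pipelineConfig, y)
}
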