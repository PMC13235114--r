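# Two-group synthetic prescription corpora with planted structure.
#
# Each prescription is assembled from three independent mechanisms whose
# union is the herb set: (i) co-prescription modules that activate as a
# block and then include each member independently, (ii) differential herbs
# with group-specific marginal frequencies, (iii) background herbs with a
# low independent inclusion probability. Sizes outside the configured range
# are rejected and the prescription resampled, which preserves the
# within-prescription dependence a truncation would destroy.

.deriveSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

#' Configuration for the synthetic two-group corpus generator
#'
#' The defaults define the generator's reference conditions: a vocabulary of
#' 210 herbs; one planted 8-herb co-prescription module activating in 60\%
#' of anti-recurrence prescriptions (30\% in the general group) and
#' including each member with probability 0.9 when active; three of the
#' module herbs additionally differential at 60\% vs 20\% marginal frequency
#' (a 40-percentage-point shift); all remaining herbs as background at 3\%;
#' 150 anti-recurrence and 120 general prescriptions clamped to 5--20 herbs.
#'
#' @param n_anti,n_general Prescriptions per group.
#' @param vocab_size Total number of herbs; names are \code{Herb001} ... and
#'   module/differential herbs are drawn from the front of that list.
#' @param modules List of module descriptors, each a list with
#'   \code{members} (character), \code{activation_prob},
#'   \code{inclusion_prob}, \code{group_bias} (multiplier on
#'   \code{activation_prob} in the general group).
#' @param background_prob Per-herb base inclusion probability.
#' @param differential_herbs data.frame with columns \code{herb},
#'   \code{freq_anti}, \code{freq_general}.
#' @param size_range Integer length-2: prescription-size clamp (rejection
#'   sampling).
#' @param seed Integer master seed; every sub-stage seed is derived from it.
#' @return A validated list of class \code{"SyntheticConfig"}.
#' @export
syntheticConfig <- function(n_anti = 150L, n_general = 120L,
                            vocab_size = 210L,
                            modules = NULL, background_prob = 0.03,
                            differential_herbs = NULL,
                            size_range = c(5L, 20L), seed = 1L) {
  vocab <- sprintf("Herb%03d", seq_len(vocab_size))
  if (is.null(modules))
    modules <- list(list(members = vocab[1:8], activation_prob = 0.6,
                         inclusion_prob = 0.9, group_bias = 0.5))
  if (is.null(differential_herbs))
    differential_herbs <- data.frame(
      herb = vocab[1:3], freq_anti = 0.6, freq_general = 0.2,
      stringsAsFactors = FALSE)
  cfg <- list(n_anti = as.integer(n_anti), n_general = as.integer(n_general),
              vocab_size = as.integer(vocab_size), vocabulary = vocab,
              modules = modules, background_prob = background_prob,
              differential_herbs = differential_herbs,
              size_range = as.integer(size_range), seed = as.integer(seed))
  probs <- c(background_prob,
             unlist(lapply(modules, function(m)
               c(m$activation_prob, m$inclusion_prob))),
             differential_herbs$freq_anti, differential_herbs$freq_general)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  named <- unique(c(unlist(lapply(modules, `[[`, "members")),
                    differential_herbs$herb))
  if (!all(named %in% vocab))
    stop("vocab_size too small for the named module/differential herbs")
  if (cfg$size_range[1] > cfg$size_range[2])
    stop("size_range must be increasing")
  class(cfg) <- "SyntheticConfig"
  cfg
}

.sampleOne <- function(cfg, group) {
  vocab <- cfg$vocabulary
  diffHerbs <- cfg$differential_herbs$herb
  moduleHerbs <- unique(unlist(lapply(cfg$modules, `[[`, "members")))
  backgroundHerbs <- setdiff(vocab, union(moduleHerbs, diffHerbs))
  diffP <- if (group == "anti_recurrence") cfg$differential_herbs$freq_anti
           else cfg$differential_herbs$freq_general
  for (try in seq_len(1000L)) {
    herbs <- character()
    for (m in cfg$modules) {
      act <- m$activation_prob *
        if (group == "general") m$group_bias else 1
      if (stats::runif(1) < act)
        herbs <- c(herbs,
                   m$members[stats::runif(length(m$members)) < m$inclusion_prob])
    }
    herbs <- c(herbs, diffHerbs[stats::runif(length(diffHerbs)) < diffP])
    herbs <- c(herbs,
               backgroundHerbs[stats::runif(length(backgroundHerbs)) <
                                 cfg$background_prob])
    herbs <- unique(herbs)
    n <- length(herbs)
    if (n >= cfg$size_range[1] && n <= cfg$size_range[2])
      return(sort(herbs))
  }
  stop("size_range infeasible: >1000 rejections for one prescription; ",
       "the expected prescription size lies far outside the clamp")
}

#' Generate a two-group prescription corpus with known ground truth
#'
#' Samples \code{n_anti} + \code{n_general} prescriptions under the
#' mechanism described in \code{\link{syntheticConfig}}. Fully reproducible:
#' the same configuration (including its seed) yields the same corpus.
#'
#' @param config A \code{\link{syntheticConfig}}.
#' @return List with \code{corpus} (a \linkS4class{PrescriptionCorpus};
#'   prescription ids \code{A001...}/\code{G001...}) and \code{truth} (list
#'   with \code{planted_modules}, a list of herb sets, and
#'   \code{planted_differentials}, the differential table).
#' @examples
#' sim <- generateTwoGroupCorpus(syntheticConfig(n_anti = 30, n_general = 20))
#' sim$corpus
#' @export
generateTwoGroupCorpus <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(.deriveSeed(config$seed, "two_group_corpus"))
  anti <- lapply(seq_len(config$n_anti), function(i)
    .sampleOne(config, "anti_recurrence"))
  gen <- lapply(seq_len(config$n_general), function(i)
    .sampleOne(config, "general"))
  names(anti) <- sprintf("A%03d", seq_along(anti))
  names(gen) <- sprintf("G%03d", seq_along(gen))
  corpus <- PrescriptionCorpus(
    c(anti, gen),
    c(rep("anti_recurrence", length(anti)), rep("general", length(gen))),
    deduplicate = FALSE)   # sampled ids are distinct; duplicates legitimate
  truth <- list(
    planted_modules = lapply(config$modules, `[[`, "members"),
    planted_differentials = config$differential_herbs)
  list(corpus = corpus, truth = truth)
}

# Save/restore the global RNG state so generators behave as pure functions
# of their seed argument.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Synthetic compound and target tables for the screening arm
#'
#' Emulates database exports for the network-pharmacology filters: compounds
#' carry oral bioavailability (OB, percent, uniform on 0--60) and
#' drug-likeness (DL, uniform on 0--0.5) scores; target links carry SVM and
#' RF prediction scores uniform on 0--1. Each record is first assigned
#' pass/fail with probability \code{pass_fraction} and its scores then drawn
#' from the corresponding side of the screening thresholds (OB >= 30 with
#' DL >= 0.18; SVM >= 0.8 with RF >= 0.7), so the expected surviving
#' fraction equals \code{pass_fraction} exactly.
#'
#' @param n_compounds,n_targets Row counts for the two tables.
#' @param pass_fraction Probability a record satisfies its filter.
#' @param seed Integer seed.
#' @return List with \code{compounds} (herb, compound_id, compound_name, ob,
#'   dl) and \code{targets} (compound_id, gene_symbol, svm_score, rf_score).
#' @export
generateNetpharmTables <- function(n_compounds, n_targets,
                                   pass_fraction = 0.5, seed = 1L) {
  stopifnot(n_compounds > 0, n_targets > 0,
            pass_fraction >= 0, pass_fraction <= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(.deriveSeed(seed, "netpharm_tables"))
  drawSide <- function(n, lo, hi, cut, pass) {
    # uniform on [lo, hi], conditioned above (pass) or below (fail) cut
    if (pass) stats::runif(n, cut, hi) else stats::runif(n, lo, cut)
  }
  passC <- stats::runif(n_compounds) < pass_fraction
  ob <- dl <- numeric(n_compounds)
  # a failing compound misses at least one of the two thresholds
  failMode <- sample(3L, n_compounds, replace = TRUE)  # 1: ob, 2: dl, 3: both
  for (i in seq_len(n_compounds)) {
    if (passC[i]) {
      ob[i] <- drawSide(1, 0, 60, 30, TRUE)
      dl[i] <- drawSide(1, 0, 0.5, 0.18, TRUE)
    } else {
      obFail <- failMode[i] %in% c(1L, 3L)
      dlFail <- failMode[i] %in% c(2L, 3L)
      ob[i] <- drawSide(1, 0, 60, 30, !obFail)
      dl[i] <- drawSide(1, 0, 0.5, 0.18, !dlFail)
    }
  }
  compounds <- data.frame(
    herb = sprintf("Herb%03d", sample(8L, n_compounds, replace = TRUE)),
    compound_id = sprintf("CMP%04d", seq_len(n_compounds)),
    compound_name = sprintf("compound_%04d", seq_len(n_compounds)),
    ob = ob, dl = dl, stringsAsFactors = FALSE)
  passT <- stats::runif(n_targets) < pass_fraction
  failModeT <- sample(3L, n_targets, replace = TRUE)
  svm <- rf <- numeric(n_targets)
  for (i in seq_len(n_targets)) {
    if (passT[i]) {
      svm[i] <- drawSide(1, 0, 1, 0.8, TRUE)
      rf[i] <- drawSide(1, 0, 1, 0.7, TRUE)
    } else {
      svmFail <- failModeT[i] %in% c(1L, 3L)
      rfFail <- failModeT[i] %in% c(2L, 3L)
      svm[i] <- drawSide(1, 0, 1, 0.8, !svmFail)
      rf[i] <- drawSide(1, 0, 1, 0.7, !rfFail)
    }
  }
  targets <- data.frame(
    compound_id = compounds$compound_id[
      sample(n_compounds, n_targets, replace = TRUE)],
    gene_symbol = sprintf("GENE%03d", sample(60L, n_targets, replace = TRUE)),
    svm_score = svm, rf_score = rf, stringsAsFactors = FALSE)
  list(compounds = compounds, targets = targets)
}
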