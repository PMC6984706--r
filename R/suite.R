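#' Preset benchmark phylogenies
#'
#' Three standard family layouts: `pairwise` (two leaves of 3,000 and
#' 4,000 nodes evolved from a 2,000-node ancestor), `5way` (five leaves
#' of 1,250/1,500/1,750/2,000/2,000 nodes) and `8way` (eight leaves of
#' 1,000 nodes). Internal-node sizes interpolate monotonically between
#' root and leaves (midpoint rule). The trees ship as packaged text
#' files under `extdata/trees`.
#'
#' @param name One of `"pairwise"`, `"5way"`, `"8way"`.
#' @return The root [PhylogenyNode-class].
#' @examples
#' phylogenyLeaves(presetTree("pairwise"))
#' @export
presetTree <- function(name = c("pairwise", "5way", "8way")) {
  name <- match.arg(name)
  f <- system.file("extdata", "trees", paste0(name, ".tree"),
                   package = "ppifam", mustWork = TRUE)
  parsePhylogeny(file = f)
}

#' Plan a benchmark suite build
#'
#' Enumerates every family of the requested suite(s) without generating
#' any network: one row per family with its suite, growth model, family
#' index, derived seed and leaf-network count. The default full plan
#' (three suites, four models, ten families each) comprises 120
#' families and 600 networks.
#'
#' @param name `"pairwise"`, `"5way"`, `"8way"` or `"all"`.
#' @param familiesPerModel Families per growth model and suite.
#' @param models Character vector of growth models.
#' @param seed Master seed; per-family seeds are derived from it by a
#'   deterministic counter scheme (distinct within a plan).
#' @return `data.frame` with columns `suite`, `model`, `family`,
#'   `seed`, `networks`.
#' @examples
#' plan <- planSuite("all", seed = 1)
#' nrow(plan)            # 120 families
#' sum(plan$networks)    # 600 networks
#' @export
planSuite <- function(name = c("all", "pairwise", "5way", "8way"),
                      familiesPerModel = 10L,
                      models = c("dmc", "dmr", "cg", "sticky"),
                      seed = 1L) {
  name <- match.arg(name)
  suites <- if (name == "all") c("pairwise", "5way", "8way") else name
  nets <- c(pairwise = 2L, `5way` = 5L, `8way` = 8L)
  rows <- expand.grid(family = seq_len(familiesPerModel),
                      model = models, suite = suites,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- rows[, c("suite", "model", "family")]
  rows$seed <- .deriveSeed(seed, seq_len(nrow(rows)))
  rows$networks <- nets[rows$suite]
  rownames(rows) <- NULL
  rows
}

# Counter-based derivation: distinct, reproducible, < 2^31.
.deriveSeed <- function(master, counter) {
  (as.integer(master) %% 1000000L) * 1000L + as.integer(counter)
}

#' Build benchmark suites on disk
#'
#' Generates every family of [planSuite()] with [synthesizeFamily()] and
#' writes it with [writeFamily()] under
#' `outDir/<suite>/<model>/family_<i>/`; a global `manifest.json` at the
#' top level aggregates family counts, network counts and the derived
#' seeds. Partial output of a failed family is removed.
#'
#' @inheritParams planSuite
#' @param outDir Output directory.
#' @param quiet Suppress per-phase progress lines on stderr.
#' @return Invisibly, the global manifest list.
#' @export
buildSuite <- function(name = c("all", "pairwise", "5way", "8way"),
                       outDir, seed = 1L, familiesPerModel = 10L,
                       models = c("dmc", "dmr", "cg", "sticky"),
                       quiet = FALSE) {
  name <- match.arg(name)
  plan <- planSuite(name, familiesPerModel, models, seed)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  built <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    row <- plan[i, ]
    famDir <- file.path(outDir, row$suite, row$model,
                        paste0("family_", row$family))
    if (!quiet)
      message(sprintf("[%s/%s] family %d (seed %d): synthesizing",
                      row$suite, row$model, row$family, row$seed))
    ok <- tryCatch({
      fam <- synthesizeFamily(presetTree(row$suite), modelParams(row$model),
                              seed = row$seed)
      if (!quiet) {
        cnt <- vapply(fam@networks, nodeCount, integer(1))
        message(sprintf("  grown %d networks (%s nodes); writing",
                        length(cnt), paste(cnt, collapse = "/")))
      }
      writeFamily(fam, famDir)
      TRUE
    }, error = function(e) {
      unlink(famDir, recursive = TRUE)
      stop("family build failed (", famDir, "): ", conditionMessage(e))
    })
    built[[i]] <- list(suite = row$suite, model = row$model,
                       family = row$family, seed = row$seed,
                       path = famDir)
  }
  manifest <- list(master_seed = seed,
                   families = nrow(plan),
                   networks = sum(plan$networks),
                   plan = built)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
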