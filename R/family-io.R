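#' Write a family bundle to disk
#'
#' Serializes a [FamilyBundle-class] into the benchmark layout: one
#' `<net>.net` tab-separated edge list per network, one
#' `<netA>-<netB>.sim` similarity file per unordered network pair
#' (columns `node_a node_b score`, scores printed with 6 significant
#' digits), an `orthology.tsv` ground-truth file (one FO group spanning
#' at least two networks per line: group id then `network:node`
#' members), and a `manifest.json` with sizes, model, parameters and
#' seed. All files are sorted canonically, so output is byte-stable for
#' a fixed generation seed.
#'
#' @param bundle A [FamilyBundle-class]; networks must be singleton-free
#'   and FO-consistent (validated before any write).
#' @param outDir Output directory (created if needed).
#' @return Invisibly, a named list of written paths (`networks`,
#'   `similarities`, `orthology`, `manifest`).
#' @export
writeFamily <- function(bundle, outDir) {
  stopifnot(is(bundle, "FamilyBundle"))
  validObject(bundle)
  # validate before any write
  for (nw in bundle@networks) {
    deg <- nodeDegree(nw)
    if (any(deg == 0L))
      stop("network '", nw@name, "' has singleton nodes; refusing to write")
  }
  g <- bundle@groups
  if (nrow(g)) {
    for (i in seq_len(nrow(g))) {
      nw <- bundle@networks[[g$network[i]]]
      if (is.null(nw) || !g$node[i] %in% nodeIds(nw))
        stop("FO group member ", g$network[i], ":", g$node[i],
             " does not exist in the bundle")
      if (!identical(unname(foAnnotation(nw)[g$node[i]]), g$group[i]))
        stop("FO inconsistency for ", g$network[i], ":", g$node[i])
    }
  }
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outDir)) stop("cannot create output directory ", outDir)

  paths <- list(networks = character(), similarities = character())
  for (nw in bundle@networks) {
    p <- file.path(outDir, paste0(nw@name, ".net"))
    e <- edgeMatrix(nw)
    writeLines(paste(e[, 1L], e[, 2L], sep = "\t"), p)
    paths$networks <- c(paths$networks, p)
  }

  nets <- sort(names(bundle@networks))
  sims <- bundle@similarities
  if (length(nets) >= 2L) {
    prs <- utils::combn(nets, 2L)
    for (i in seq_len(ncol(prs))) {
      a <- prs[1L, i]; b <- prs[2L, i]
      p <- file.path(outDir, paste0(a, "-", b, ".sim"))
      sel <- sims[(sims$net_a == a & sims$net_b == b) |
                    (sims$net_a == b & sims$net_b == a), , drop = FALSE]
      if (nrow(sel)) {
        flip <- sel$net_a != a
        tmp <- sel
        sel$node_a[flip] <- tmp$node_b[flip]
        sel$node_b[flip] <- tmp$node_a[flip]
        sel <- sel[order(sel$node_a, sel$node_b), , drop = FALSE]
      }
      writeLines(if (nrow(sel))
        paste(sel$node_a, sel$node_b, sprintf("%.6g", sel$score), sep = "\t")
        else character(), p)
      paths$similarities <- c(paths$similarities, p)
    }
  }

  orthPath <- file.path(outDir, "orthology.tsv")
  lines <- character()
  if (nrow(g)) {
    sp <- split(g, g$group)
    sp <- sp[vapply(sp, function(x) length(unique(x$network)) >= 2L, logical(1))]
    ids <- sort(names(sp))
    lines <- vapply(ids, function(id) {
      m <- sp[[id]]
      m <- m[order(m$network, m$node), ]
      paste(c(id, paste0(m$network, ":", m$node)), collapse = "\t")
    }, character(1))
  }
  writeLines(lines, orthPath)
  paths$orthology <- orthPath

  manPath <- file.path(outDir, "manifest.json")
  jsonlite::write_json(bundle@manifest, manPath, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  paths$manifest <- manPath
  invisible(paths)
}
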