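#' Representative (consensus) spectrum of a scan group
#'
#' Concatenates the peak lists of all scans that share a precursor chain and
#' merges fragment ions within the tolerance: each mass bin contributes one
#' peak at the median of the member m/z values, with intensity aggregated by
#' the maximum or the 95% quantile. Using every available scan (rather than
#' singling one out) lets the scan-to-scan variation of fragmentation
#' spectra be assessed.
#'
#' @param group a `scan_group` from [group_by_chain()].
#' @param tol fragment merging tolerance.
#' @param agg `"max"` (default) or `"q95"`.
#' @return object of class `rep_spectrum` (`chain`, `peaks`, `n_scans`,
#'   `agg`, `sample_id`).
#' @export
representative_spectrum <- function(group, tol, agg = c("max", "q95")) {
  agg <- match.arg(agg)
  stopifnot(inherits(group, "scan_group"), length(group$scans) > 0L)
  all_peaks <- do.call(rbind, lapply(group$scans, `[[`, "peaks"))
  merged <- merge_peaks(all_peaks, tol, agg)
  samples <- unique(vapply(group$scans, `[[`, "", "sample_id"))
  structure(list(chain = group$chain_center, peaks = merged,
                 n_scans = length(group$scans), agg = agg,
                 sample_id = if (length(samples) == 1L) samples else NA_character_),
            class = "rep_spectrum")
}

#' @export
print.rep_spectrum <- function(x, ...) {
  chain <- if (length(x$chain)) paste(sprintf("%.4f", x$chain), collapse = " > ") else "-"
  cat(sprintf("<rep_spectrum> chain=[%s] %d peaks from %d scans (agg=%s)\n",
              chain, nrow(x$peaks), x$n_scans, x$agg))
  invisible(x)
}

#' Remove weak scans before tree construction
#'
#' Weak spectra tend to show large scan-to-scan variation, so scans whose
#' base-peak intensity falls below the threshold (default 100 arbitrary
#' units) are removed. Scans with no peaks are always removed.
#'
#' @param scans list of [msn_scan()] objects.
#' @param min_base_peak minimum base-peak intensity to retain (default 100).
#' @return filtered scan list.
#' @export
qc_filter_spectra <- function(scans, min_base_peak = 100) {
  stopifnot(min_base_peak >= 0)
  Filter(function(s) base_peak_intensity(s) >= min_base_peak, scans)
}

#' Build ion trees for one MS^1 bin
#'
#' Scans whose chain starts within `root_mz` +/- the half-window are used.
#' For each sample, all MS^2 scans (chain `[root]`) are grouped into one
#' MS^2 node and the MS^3 scans into one node per distinct
#' `(root, MS^2-product)` chain, each node holding the representative
#' spectrum over its scans. A sample without MS^2 scans yields a tree with
#' no nodes (valid, but flagged by a message).
#'
#' @param scans list of [msn_scan()] objects.
#' @param root_mz MS^1 bin center (Th).
#' @param tol grouping/merging tolerance.
#' @param agg intensity aggregation for representative spectra.
#' @return named list of `ion_tree` objects, one per sample.
#' @export
build_tree <- function(scans, root_mz, tol, agg = c("max", "q95")) {
  agg <- match.arg(agg)
  keep <- Filter(function(s)
    s$ms_level >= 2L && mz_within(s$precursor_chain[1], root_mz, tol), scans)
  samples <- sort(unique(vapply(keep, `[[`, "", "sample_id")))
  if (length(samples) == 0L) samples <- character(0)
  trees <- lapply(samples, function(sid) {
    sc <- Filter(function(s) s$sample_id == sid, keep)
    groups <- group_by_chain(sc, tol)
    ms2 <- Filter(function(g) g$ms_level == 2L, groups)
    ms3 <- Filter(function(g) g$ms_level == 3L, groups)
    if (length(ms2) == 0L)
      message(sprintf("sample %s: no MS2 scans in bin %g; empty tree", sid, root_mz))
    structure(list(root_mz = root_mz, sample_id = sid,
                   ms2_nodes = lapply(ms2, representative_spectrum, tol = tol, agg = agg),
                   ms3_nodes = lapply(ms3, representative_spectrum, tol = tol, agg = agg),
                   annotation = NULL),
              class = "ion_tree")
  })
  names(trees) <- samples
  trees
}

#' Number of MS^3 nodes of a tree (its branching count)
#'
#' @param tree an `ion_tree`.
#' @return integer.
#' @export
n_ms3 <- function(tree) length(tree$ms3_nodes)

#' @export
print.ion_tree <- function(x, ...) {
  cat(sprintf("<ion_tree> root m/z %g, sample=%s: %d MS2 node(s), %d MS3 node(s)%s\n",
              x$root_mz, x$sample_id, length(x$ms2_nodes), n_ms3(x),
              if (is.null(x$annotation)) "" else paste0(' "', x$annotation, '"')))
  invisible(x)
}

#' Select the most-branched tree across samples
#'
#' Of the trees built for one MS^1 bin across samples, only the one with
#' the highest number of MS^3 spectra is retained for deposit into the
#' library: the most branched tree captures the most information on the
#' fragmentation pathways of the ion. Ties are broken by the larger summed
#' base-peak intensity over MS^2 nodes, then by the smallest sample id.
#'
#' @param trees list of `ion_tree` objects for one root m/z.
#' @return the selected `ion_tree`.
#' @export
select_most_branched <- function(trees) {
  stopifnot(length(trees) > 0L)
  score_bp <- function(t) sum(vapply(t$ms2_nodes, function(n)
    if (nrow(n$peaks)) max(n$peaks[, "intensity"]) else 0, numeric(1)))
  nms3 <- vapply(trees, n_ms3, integer(1))
  bp <- vapply(trees, score_bp, numeric(1))
  sid <- vapply(trees, `[[`, "", "sample_id")
  trees[[order(-nms3, -bp, sid)[1L]]]
}

#' Serialize a nominal-mass tree to the literature text notation
#'
#' Renders the notation used to publish spectral trees, e.g.
#' `"248-206 (175, 149), 231"`: the precursor ion m/z 248 has major MS^2
#' product ions m/z 206 and 231, and the MS^2 ion m/z 206 in turn gives the
#' MS^3 product ions m/z 175 and 149. Children are the MS^2 product ions in
#' descending representative intensity; a child with an MS^3 node lists up
#' to `top_k_ms3_ions` of its product ions, also by descending intensity.
#' m/z values are rounded to integers (nominal mass); the dash written is
#' ASCII hyphen-minus.
#'
#' @param tree an `ion_tree`.
#' @param top_k_ms3_ions maximum MS^3 product ions listed per child.
#' @param tol tolerance used to attach MS^3 chains to MS^2 product ions.
#' @return single character string ("" for an empty tree).
#' @export
tree_to_text <- function(tree, top_k_ms3_ions = 2, tol = tol_da(0.5)) {
  if (length(tree$ms2_nodes) == 0L) {
    if (n_ms3(tree) == 0L && !is.null(tree$root_mz)) return("")
    return("")
  }
  root <- round(tree$root_mz)
  ms2 <- tree$ms2_nodes[[1L]]
  if (nrow(ms2$peaks) == 0L) return(sprintf("%d", root))
  prods <- ms2$peaks[order(-ms2$peaks[, "intensity"], ms2$peaks[, "mz"]), , drop = FALSE]
  parts <- character(nrow(prods))
  for (i in seq_len(nrow(prods))) {
    child_mz <- prods[i, "mz"]
    node <- Filter(function(n) length(n$chain) == 2L &&
                     mz_within(n$chain[2], child_mz, tol), tree$ms3_nodes)
    lab <- sprintf("%d", round(child_mz))
    if (length(node)) {
      gp <- node[[1L]]$peaks
      gp <- gp[order(-gp[, "intensity"], gp[, "mz"]), , drop = FALSE]
      gp <- gp[seq_len(min(top_k_ms3_ions, nrow(gp))), , drop = FALSE]
      if (nrow(gp))
        lab <- sprintf("%s (%s)", lab,
                       paste(sprintf("%d", round(gp[, "mz"])), collapse = ", "))
    }
    parts[i] <- lab
  }
  sprintf("%d-%s", root, paste(parts, collapse = ", "))
}

#' Parse the text notation of a spectral tree
#'
#' Accepts hyphen-minus or en-dash between root and first child. Returns the
#' topology only (m/z values; intensities are not part of the notation).
#'
#' @param text tree notation, e.g. `"248-206 (175, 149), 231"`.
#' @return list with `root` (numeric) and `children`, a list of
#'   `list(mz =, ms3 =)` in listed order.
#' @export
parse_text_tree <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- gsub("–", "-", text)  # en-dash -> hyphen-minus
  if (!nzchar(trimws(s))) stop("empty tree text at position 1")
  num_re <- "[0-9]+(\\.[0-9]+)?"
  m <- regexpr(sprintf("^\\s*(%s)", num_re), s)
  if (m == -1L) stop("expected root m/z at position 1")
  root_tok <- trimws(regmatches(s, m))
  rest <- substr(s, attr(m, "match.length") + 1L, nchar(s))
  pos <- attr(m, "match.length") + 1L
  children <- list()
  if (nzchar(trimws(rest))) {
    rest2 <- trimws(rest)
    if (!startsWith(rest2, "-"))
      stop(sprintf("expected '-' after root at position %d", pos))
    body <- sub("^\\s*-", "", rest)
    # split children on commas that are not inside parentheses
    toks <- character(0)
    depth <- 0L; start <- 1L
    chars <- strsplit(body, "")[[1]]
    for (i in seq_along(chars)) {
      ch <- chars[i]
      if (ch == "(") depth <- depth + 1L
      else if (ch == ")") {
        depth <- depth - 1L
        if (depth < 0L) stop(sprintf("unbalanced ')' at position %d", pos + i))
      } else if (ch == "," && depth == 0L) {
        toks <- c(toks, substr(body, start, i - 1L)); start <- i + 1L
      }
    }
    if (depth != 0L) stop("unbalanced '(' in tree text")
    toks <- c(toks, substr(body, start, nchar(body)))
    children <- lapply(seq_along(toks), function(k) {
      tk <- trimws(toks[k])
      cm <- regexpr(sprintf("^(%s)", num_re), tk)
      if (cm == -1L) stop(sprintf("expected child m/z in segment %d ('%s')", k, tk))
      child_mz <- as.numeric(regmatches(tk, cm))
      tail <- trimws(substr(tk, attr(cm, "match.length") + 1L, nchar(tk)))
      ms3 <- numeric(0)
      if (nzchar(tail)) {
        if (!grepl(sprintf("^\\((\\s*%s\\s*)(,\\s*%s\\s*)*\\)$", num_re, num_re), tail))
          stop(sprintf("malformed MS3 list in segment %d ('%s')", k, tail))
        inner <- sub("^\\(", "", sub("\\)$", "", tail))
        ms3 <- as.numeric(trimws(strsplit(inner, ",")[[1]]))
      }
      list(mz = child_mz, ms3 = ms3)
    })
  }
  list(root = as.numeric(root_tok), children = children)
}

#' Export an ion tree as JSON
#'
#' Full interchange export: chains, peak lists and scan counts of every
#' node. [tree_from_json()] reads it back.
#'
#' @param tree an `ion_tree`.
#' @param path optional file; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly, when written to a file).
#' @export
tree_to_json <- function(tree, path = NULL) {
  node_list <- function(n) list(chain = n$chain,
                                mz = n$peaks[, "mz"],
                                intensity = n$peaks[, "intensity"],
                                n_scans = n$n_scans, agg = n$agg)
  obj <- list(root_mz = tree$root_mz, sample_id = tree$sample_id,
              annotation = tree$annotation,
              ms2_nodes = lapply(tree$ms2_nodes, node_list),
              ms3_nodes = lapply(tree$ms3_nodes, node_list))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' @rdname tree_to_json
#' @param json JSON string or path to a JSON file.
#' @export
tree_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  mk_node <- function(n) structure(
    list(chain = as.numeric(unlist(n$chain)),
         peaks = new_peaks(as.numeric(unlist(n$mz)), as.numeric(unlist(n$intensity))),
         n_scans = as.integer(n$n_scans), agg = n$agg,
         sample_id = obj$sample_id),
    class = "rep_spectrum")
  structure(list(root_mz = as.numeric(obj$root_mz), sample_id = obj$sample_id,
                 ms2_nodes = lapply(obj$ms2_nodes, mk_node),
                 ms3_nodes = lapply(obj$ms3_nodes, mk_node),
                 annotation = obj$annotation),
            class = "ion_tree")
}
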