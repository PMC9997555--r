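# Line-exclusion rules: cross-contamination between dish mates and the
# minimum-depth floor. Both filters partition the input (kept + removed)
# and are idempotent; mutations of removed lines are excluded from all
# downstream counts and exposures.

#' Remove cross-contaminated dish mates
#'
#' Two MA lines propagated on the same Petri dish are candidate
#' contamination pairs. If the two lines on a dish share at least one
#' identical mutation (same chromosome, position, REF and ALT), the line
#' whose line-id carries an even trailing number is removed as the
#' contaminated one. A pair sharing several mutations still removes only
#' that one line.
#'
#' @param mutations Mutation data.frame (line_id, chromosome, position,
#'   ref, alt).
#' @param lines Line-metadata data.frame with line_id and dish_id.
#' @return List with `kept`, `removed` (metadata subsets) and `report`
#'   (one row per removal with the first shared site).
#' @export
contamination_filter <- function(mutations, lines) {
  stopifnot(all(c("line_id", "dish_id") %in% names(lines)))
  dishes <- split(lines$line_id, lines$dish_id)
  sizes <- lengths(dishes)
  if (any(sizes > 2L)) {
    stop("dish ", names(dishes)[which(sizes > 2L)[1]], " holds ",
         max(sizes), " lines; the contamination rule is defined for pairs")
  }
  key <- paste(mutations$chromosome, mutations$position, mutations$ref,
               mutations$alt, sep = ":")
  removed_ids <- character(0)
  report <- list()
  for (d in names(dishes)[sizes == 2L]) {
    ln <- dishes[[d]]
    k1 <- key[mutations$line_id == ln[1]]
    k2 <- key[mutations$line_id == ln[2]]
    shared <- intersect(k1, k2)
    if (!length(shared)) next
    suffix <- as.integer(sub(".*?(\\d+)$", "\\1", ln))
    if (anyNA(suffix)) {
      stop("line ids on dish ", d, " carry no numeric suffix: ",
           paste(ln, collapse = ", "))
    }
    even <- ln[suffix %% 2L == 0L]
    if (!length(even)) even <- ln[2]  # both odd: remove the later line
    removed_ids <- c(removed_ids, even[1])
    report[[length(report) + 1L]] <- data.frame(
      line_id = even[1], dish_id = d, rule = "contamination",
      shared_site = shared[1], n_shared = length(shared),
      stringsAsFactors = FALSE)
  }
  report <- if (length(report)) do.call(rbind, report) else
    data.frame(line_id = character(), dish_id = character(),
               rule = character(), shared_site = character(),
               n_shared = integer(), stringsAsFactors = FALSE)
  list(kept = lines[!lines$line_id %in% removed_ids, , drop = FALSE],
       removed = lines[lines$line_id %in% removed_ids, , drop = FALSE],
       report = report)
}

#' Remove lines below the sequencing-depth floor
#'
#' @param lines Line-metadata data.frame with mean_depth.
#' @param min_depth Minimum acceptable mean fold-coverage (default 30).
#' @return List with `kept` and `removed` metadata subsets.
#' @export
depth_filter <- function(lines, min_depth = 30) {
  stopifnot("mean_depth" %in% names(lines))
  low <- lines$mean_depth < min_depth
  list(kept = lines[!low, , drop = FALSE],
       removed = lines[low, , drop = FALSE])
}

#' Apply the full line-QC (contamination then depth)
#'
#' @inheritParams contamination_filter
#' @inheritParams depth_filter
#' @return List with `kept`, `removed`, `report` (per-removal rows) and
#'   `mutations` restricted to kept lines.
#' @export
qc_lines <- function(mutations, lines, min_depth = 30) {
  cf <- contamination_filter(mutations, lines)
  df <- depth_filter(cf$kept, min_depth = min_depth)
  depth_report <- if (nrow(df$removed)) {
    data.frame(line_id = df$removed$line_id, dish_id = df$removed$dish_id,
               rule = "depth", shared_site = NA_character_,
               n_shared = NA_integer_, stringsAsFactors = FALSE)
  } else NULL
  report <- rbind(cf$report, depth_report)
  removed <- rbind(cf$removed, df$removed)
  list(kept = df$kept, removed = removed, report = report,
       mutations = mutations[mutations$line_id %in% df$kept$line_id, ,
                             drop = FALSE])
}
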