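# Parent-child object relation: assign each child cluster (segmented from
# the raw super-resolved image) to the fused parent domain it overlaps
# most, then count children per parent.  This is the quantification step
# that turns two label maps into "clusters per nuclear pore".

#' Relate child objects to parent objects
#'
#' Each child is assigned to the parent label with which it shares the most
#' pixels; children overlapping no parent get `parent_label` 0.  Overlap
#' ties go to the smaller parent label.  Maximal-overlap assignment (rather
#' than centroid containment) is deliberate: the centroid of a ring-shaped
#' parent's child can fall in the ring's central hole.
#'
#' Both label maps must come from the same (already aligned) image; no
#' registration is performed, only a shape check.
#'
#' @param parents,children Integer label matrices of identical shape.
#' @return A list of class `sr_relation`: `children` (data.frame
#'   `child_label`, `parent_label`, `overlap_px`) and `parents` (data.frame
#'   `parent_label`, `child_count`, zero-child parents included).
#' @export
relate_objects <- function(parents, children) {
  if (!all(dim(parents) == dim(children)))
    stop_srseg("parent and child label maps have different dimensions",
               "dimension")
  n_child <- max(children, 0L)
  n_parent <- max(parents, 0L)
  child_tab <- data.frame(child_label = seq_len(n_child),
                          parent_label = rep(0L, n_child),
                          overlap_px = rep(0L, n_child))
  if (n_child > 0L && n_parent > 0L) {
    both <- which(children > 0L & parents > 0L)
    if (length(both)) {
      ov <- stats::aggregate(
        list(overlap_px = rep.int(1L, length(both))),
        by = list(child_label = children[both], parent_label = parents[both]),
        FUN = sum)
      # best parent per child: max overlap, ties to the smaller parent label
      ov <- ov[order(ov$child_label, -ov$overlap_px, ov$parent_label), ]
      best <- ov[!duplicated(ov$child_label), ]
      child_tab$parent_label[best$child_label] <- best$parent_label
      child_tab$overlap_px[best$child_label] <- best$overlap_px
    }
  }
  counts <- tabulate(child_tab$parent_label[child_tab$parent_label > 0L],
                     nbins = n_parent)
  parent_tab <- data.frame(parent_label = seq_len(n_parent),
                           child_count = if (n_parent) counts else integer(0))
  structure(list(children = child_tab, parents = parent_tab),
            class = "sr_relation")
}

#' @export
print.sr_relation <- function(x, ...) {
  cat(sprintf("<sr_relation> %d children over %d parents (%d unassigned)\n",
              nrow(x$children), nrow(x$parents),
              sum(x$children$parent_label == 0L)))
  invisible(x)
}

#' Histogram of children per parent
#'
#' @param rt An `sr_relation` from [relate_objects()].
#' @param include_empty_parents Include parents with zero children as a
#'   0-count bin contribution (default TRUE: an empty pore is still a pore).
#' @return A data.frame of class `sr_histogram` with columns `child_count`
#'   (sorted distinct counts) and `frequency`, plus attribute `mode` (the
#'   count with highest frequency; ties to the smallest).
#' @export
children_per_parent_histogram <- function(rt, include_empty_parents = TRUE) {
  stopifnot(inherits(rt, "sr_relation"))
  counts <- rt$parents$child_count
  if (!include_empty_parents) counts <- counts[counts > 0L]
  if (length(counts) == 0L)
    stop_srseg("no parents to build a histogram from", "degenerate")
  tab <- table(counts)
  h <- data.frame(child_count = as.integer(names(tab)),
                  frequency = as.integer(tab))
  h <- h[order(h$child_count), , drop = FALSE]
  rownames(h) <- NULL
  attr(h, "mode") <- h$child_count[which.max(h$frequency)]  # ties -> smallest
  class(h) <- c("sr_histogram", "data.frame")
  h
}

#' Modal children-per-parent count
#' @param h An `sr_histogram`.
#' @return The most frequent child count (ties broken to the smallest).
#' @export
histogram_mode <- function(h) attr(h, "mode")

#' Mean children per parent
#'
#' Arithmetic mean of the per-parent child counts, zero-child parents
#' included (an average of "1 cluster per pore" is an average over all
#' pores).
#'
#' @param rt An `sr_relation`.
#' @return Non-negative real.
#' @export
mean_children_per_parent <- function(rt) {
  stopifnot(inherits(rt, "sr_relation"))
  if (nrow(rt$parents) == 0L)
    stop_srseg("no parents to average over", "degenerate")
  mean(rt$parents$child_count)
}
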