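#' Enhancer-RNA containment analysis
#'
#' Marks each region as eRNA-expressing when at least one eRNA interval
#' intersects it by >= 1 bp, joins the Ctr9 / RNAPII Ser2p occupancy
#' calls for the same regions, and summarizes the containment of eRNA
#' expression within Ctr9-bound regions.
#'
#' @param regions `GRanges` with ids matching the occupancy matrix rows.
#' @param ernaIntervals `GRanges` of eRNA intervals (e.g. from a GRO-seq
#'   derived BED).
#' @param occupancy An [OccupancyMatrix-class] over the same regions with
#'   `Ctr9` and `Ser2p` columns.
#' @return List: `calls` (data.frame with `region_id`, `erna_present`,
#'   `ctr9_bound`, `ser2p_bound`) and `summary` (list with `n_erna`,
#'   `n_erna_ctr9`, `n_erna_ser2p`, `containment` = |eRNA+ & Ctr9+| /
#'   |eRNA+|, `NA` when no region expresses eRNA).
#' @export
callErna <- function(regions, ernaIntervals, occupancy) {
  ids <- .regionIds(regions)
  calls <- occupancyCalls(occupancy)
  for (f in c("Ctr9", "Ser2p")) {
    if (!f %in% colnames(calls)) {
      .stopf("occupancy matrix is missing required factor column '%s'", f)
    }
  }
  if (!setequal(ids, rownames(calls))) {
    stop("region ids do not match the occupancy matrix rows",
         call. = FALSE)
  }
  present <- GenomicRanges::countOverlaps(regions, ernaIntervals,
                                          minoverlap = 1L,
                                          ignore.strand = TRUE) > 0L
  ctr9 <- calls[ids, "Ctr9"]
  ser2p <- calls[ids, "Ser2p"]
  nE <- sum(present)
  list(calls = data.frame(region_id = ids, erna_present = present,
                          ctr9_bound = unname(ctr9),
                          ser2p_bound = unname(ser2p),
                          stringsAsFactors = FALSE),
       summary = list(n_erna = nE,
                      n_erna_ctr9 = sum(present & ctr9),
                      n_erna_ser2p = sum(present & ser2p),
                      containment = if (nE == 0L) NA_real_
                                    else sum(present & ctr9) / nE))
}
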