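# Accessor generics. Slot access from user code should go through these.

#' @name accessors
#' @title Accessors for lionessRT containers
#' @description Small accessor family for the S4 containers: sample names,
#'   edge tables, module membership, and the numeric tracks/matrices.
#' @param x an object.
#' @param ... unused.
NULL

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x, ...) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setGeneric("edgeTable", function(x, ...) standardGeneric("edgeTable"))

#' @rdname accessors
#' @export
setGeneric("networkNodes", function(x, ...) standardGeneric("networkNodes"))

#' @rdname accessors
#' @export
setGeneric("moduleList", function(x, ...) standardGeneric("moduleList"))

#' @rdname accessors
#' @export
setGeneric("moduleEdges", function(x, ...) standardGeneric("moduleEdges"))

#' @rdname accessors
#' @export
setGeneric("windowRanges", function(x, ...) standardGeneric("windowRanges"))

#' @rdname accessors
#' @export
setGeneric("rtMatrix", function(x, ...) standardGeneric("rtMatrix"))

#' @rdname accessors
#' @export
setGeneric("corMatrix", function(x, ...) standardGeneric("corMatrix"))

#' @rdname accessors
#' @export
setGeneric("partialMatrix", function(x, ...) standardGeneric("partialMatrix"))

#' @rdname accessors
#' @export
setGeneric("lionessMatrix", function(x, ...) standardGeneric("lionessMatrix"))

#' Aggregate windows into replication-timing domains
#'
#' Groups contiguous windows into fixed spans (default 300 kb) and computes
#' the length-weighted mean replication-timing proxy
#' `RT_D = sum(l(w) RT_w) / sum(l(w))` over member windows with non-missing
#' `rt`. Domains whose member windows are all missing carry `NA` and are
#' excluded from similarity computations downstream.
#'
#' @param x an [RTTrackSet-class] (cohort) or a `GRanges` of windows with an
#'   `rt` metadata column (single sample).
#' @param domainSpan domain span in bp; must be >= the window size.
#' @param ... unused.
#' @return an [RTDomainSet-class], or for `GRanges` input a `GRanges` of
#'   domains with an `rt_domain` metadata column.
#' @export
setGeneric("aggregateDomains", function(x, domainSpan = 300000L, ...)
  standardGeneric("aggregateDomains"))

#' Per-sample replication-timing summaries
#'
#' Computes the length-weighted genome-wide mean of the RT proxy and the
#' length-weighted late fraction
#' `frac_late = sum(l(w) * late(w)) / sum(l(w))` over non-missing windows.
#' Lateness defaults to `rt < 0` (high methylation implies late replication,
#' hence a below-average RT proxy); `lateSign = "positive"` selects the
#' opposite printed convention.
#'
#' @param x an [RTTrackSet-class] or a single-sample `GRanges` with `rt`.
#' @param lateSign `"negative"` or `"positive"`.
#' @param ... unused.
#' @return a data.frame with columns `sample_id`, `rt_mean`, `frac_late`.
#' @export
setGeneric("sampleSummary", function(x, lateSign = c("negative", "positive"), ...)
  standardGeneric("sampleSummary"))

#' @rdname accessors
#' @export
setMethod("sampleIds", "RTTrackSet", function(x, ...) x@sampleIds)
#' @rdname accessors
#' @export
setMethod("sampleIds", "RTDomainSet", function(x, ...) x@sampleIds)
#' @rdname accessors
#' @export
setMethod("sampleIds", "LionessSet", function(x, ...) x@sampleIds)
#' @rdname accessors
#' @export
setMethod("sampleIds", "SummarizedExperiment", function(x, ...) colnames(x))

#' @rdname accessors
#' @export
setMethod("edgeTable", "GlobalNetwork", function(x, ...) x@edges)
#' @rdname accessors
#' @export
setMethod("edgeTable", "LionessSet", function(x, ...) x@edgeIndex)

#' @rdname accessors
#' @export
setMethod("networkNodes", "GlobalNetwork", function(x, ...) x@nodes)

#' @rdname accessors
#' @export
setMethod("moduleList", "ModuleSet", function(x, ...) x@modules)
#' @rdname accessors
#' @export
setMethod("moduleEdges", "ModuleSet", function(x, ...) x@edgeSets)

#' @rdname accessors
#' @export
setMethod("windowRanges", "RTTrackSet", function(x, ...) x@windows)
#' @rdname accessors
#' @export
setMethod("windowRanges", "RTDomainSet", function(x, ...) x@domains)

#' @rdname accessors
#' @export
setMethod("rtMatrix", "RTTrackSet", function(x, ...) x@rt)
#' @rdname accessors
#' @export
setMethod("rtMatrix", "RTDomainSet", function(x, ...) x@rt)

#' @rdname accessors
#' @export
setMethod("corMatrix", "CorrelationSet", function(x, ...) x@r)
#' @rdname accessors
#' @export
setMethod("partialMatrix", "CorrelationSet", function(x, ...) {
  if (!nrow(x@rho)) stop("partial correlations not computed; see partialCorrelations()")
  x@rho
})

#' @rdname accessors
#' @param what one of "q" (individualized), "all", "minus".
#' @export
setMethod("lionessMatrix", "LionessSet", function(x, what = c("q", "all", "minus"), ...) {
  switch(match.arg(what), q = x@eQ, all = x@eAll, minus = x@eMinus)
})
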