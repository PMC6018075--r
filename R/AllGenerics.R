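#' @rdname ProteinSet-class
#' @param x,object a `ProteinSet`
#' @export
setGeneric("proteinIds", function(x) standardGeneric("proteinIds"))

#' @rdname ProteinSet-class
#' @export
setGeneric("proteinSequences",
           function(x) standardGeneric("proteinSequences"))

#' @rdname ProteinSet-class
#' @export
setGeneric("maturity", function(x) standardGeneric("maturity"))

#' @rdname EpitopeCatalog-class
#' @param x,object an `EpitopeCatalog`
#' @export
setGeneric("catalogTable", function(x) standardGeneric("catalogTable"))

#' @rdname EpitopeCatalog-class
#' @export
setGeneric("epitopeNames", function(x) standardGeneric("epitopeNames"))

#' @rdname SpotTable-class
#' @param x,object a `SpotTable`
#' @export
setGeneric("spotListings", function(x) standardGeneric("spotListings"))

#' @rdname ReferencePanel-class
#' @param x,object a `ReferencePanel`
#' @export
setGeneric("panelEntries", function(x) standardGeneric("panelEntries"))

#' @rdname GliadinCensus-class
#' @param x,object a `GliadinCensus`
#' @export
setGeneric("censusTable", function(x) standardGeneric("censusTable"))

#' @rdname GliadinCensus-class
#' @export
setGeneric("epitopeCounts", function(x) standardGeneric("epitopeCounts"))

#' @rdname GliadinCensus-class
#' @export
setGeneric("censusFailures", function(x) standardGeneric("censusFailures"))

#' @rdname GliadinCensus-class
#' @param id protein identifier
#' @export
setGeneric("censusDetails", function(x, id) standardGeneric("censusDetails"))

#' @rdname CompositionSummary-class
#' @param x,object a `CompositionSummary`
#' @export
setGeneric("summaryRows", function(x) standardGeneric("summaryRows"))
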