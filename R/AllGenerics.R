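#' @rdname GeneAnnotation-class
#' @param object,x a `GeneAnnotation` or `ModuleSet`.
#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))

#' @rdname GeneAnnotation-class
#' @export
setMethod("geneIds", "GeneAnnotation", function(object) names(object@exons))

#' @rdname GeneAnnotation-class
#' @export
setGeneric("geneBiotype", function(object) standardGeneric("geneBiotype"))

#' @rdname GeneAnnotation-class
#' @export
setMethod("geneBiotype", "GeneAnnotation", function(object) object@biotype)

#' @rdname GeneAnnotation-class
#' @export
setGeneric("exonsByGene", function(object) standardGeneric("exonsByGene"))

#' @rdname GeneAnnotation-class
#' @export
setMethod("exonsByGene", "GeneAnnotation", function(object) object@exons)

#' @rdname GeneAnnotation-class
#' @param i gene ids or indices.
#' @export
setMethod("[", "GeneAnnotation", function(x, i) {
  GeneAnnotation(x@exons[i], x@biotype[i])
})

#' @rdname ModuleSet-class
#' @param object a `ModuleSet`.
#' @export
setGeneric("moduleLabels", function(object) standardGeneric("moduleLabels"))

#' @rdname ModuleSet-class
#' @export
setMethod("moduleLabels", "ModuleSet", function(object) object@labels)

#' @rdname ModuleSet-class
#' @export
setGeneric("moduleEigengenes",
  function(object) standardGeneric("moduleEigengenes"))

#' @rdname ModuleSet-class
#' @export
setMethod("moduleEigengenes", "ModuleSet",
  function(object) object@eigengenes)

#' @rdname ModuleSet-class
#' @export
setGeneric("moduleTraitTable",
  function(object) standardGeneric("moduleTraitTable"))

#' @rdname ModuleSet-class
#' @export
setMethod("moduleTraitTable", "ModuleSet",
  function(object) object@moduleTrait)
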