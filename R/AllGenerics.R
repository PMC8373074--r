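#' @export
setGeneric("fractionProbabilities",
    function(model, cbar) standardGeneric("fractionProbabilities"))

#' @export
setGeneric("expectedFraction",
    function(model, cbar) standardGeneric("expectedFraction"))

#' @export
setGeneric("assignFractions",
    function(model, cbar) standardGeneric("assignFractions"))

#' @export
setGeneric("landscapeValues",
    function(x) standardGeneric("landscapeValues"))

#' @export
setGeneric("baselineCompaction",
    function(x) standardGeneric("baselineCompaction"))

#' @export
setGeneric("plantedDepths",
    function(x) standardGeneric("plantedDepths"))

#' @export
setGeneric("compactionAt",
    function(x, genes) standardGeneric("compactionAt"))

#' @export
setGeneric("binLabels",
    function(x) standardGeneric("binLabels"))

#' @export
setGeneric("profileProportions",
    function(x) standardGeneric("profileProportions"))
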