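#' @import methods
NULL

#' @export
setGeneric("voxelValues", function(x) standardGeneric("voxelValues"))

#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @export
setGeneric("voxelOrigin", function(x) standardGeneric("voxelOrigin"))

#' @export
setGeneric("valueUnit", function(x) standardGeneric("valueUnit"))

#' @export
setGeneric("voxelVolumeCc", function(x) standardGeneric("voxelVolumeCc"))

#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))

#' @export
setGeneric("voiName", function(x) standardGeneric("voiName"))

#' @export
setGeneric("curveTimes", function(x) standardGeneric("curveTimes"))

#' @export
setGeneric("curveActivities", function(x) standardGeneric("curveActivities"))

#' @export
setGeneric("curveSds", function(x) standardGeneric("curveSds"))

#' @export
setGeneric("meanEnergy", function(x) standardGeneric("meanEnergy"))

#' @export
setGeneric("endpointEnergy", function(x) standardGeneric("endpointEnergy"))

#' @export
setGeneric("doseValues", function(x) standardGeneric("doseValues"))

#' @export
setGeneric("relUncertainty", function(x) standardGeneric("relUncertainty"))
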