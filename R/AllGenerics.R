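#' @name radct-generics
#' @title Accessor generics
#' @description Small accessor generics used across the package's S4 classes.
#' @param x an object
#' @param object an object
#' @return The slot value; see the class documentation.
NULL

#' @rdname radct-generics
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' @rdname radct-generics
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname radct-generics
#' @export
setGeneric("volumeLabel", function(x) standardGeneric("volumeLabel"))

#' @rdname radct-generics
#' @export
setGeneric("textureMapList", function(x) standardGeneric("textureMapList"))

#' @rdname radct-generics
#' @export
setGeneric("selectedMap", function(x) standardGeneric("selectedMap"))

#' @rdname radct-generics
#' @export
setGeneric("importanceTable", function(x) standardGeneric("importanceTable"))

#' @rdname radct-generics
#' @export
setGeneric("combinedAUC", function(x) standardGeneric("combinedAUC"))

#' @rdname radct-generics
#' @export
setGeneric("foldMetrics", function(x) standardGeneric("foldMetrics"))

#' @rdname radct-generics
#' @export
setGeneric("pooledScores", function(x) standardGeneric("pooledScores"))
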