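#' @rdname SpectralCube-class
#' @param x,object a `SpectralCube`
#' @export
setGeneric("reflectance", function(x) standardGeneric("reflectance"))

#' @rdname SpectralCube-class
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @rdname SpectralCube-class
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))

#' @rdname SpectralCube-class
#' @param value replacement value
#' @export
setGeneric("validMask<-", function(x, value) standardGeneric("validMask<-"))

#' @rdname SpectralCube-class
#' @export
setGeneric("geotransform", function(x) standardGeneric("geotransform"))

#' @rdname FeatureMatrix-class
#' @param x,object a `FeatureMatrix`
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname FeatureMatrix-class
#' @export
setGeneric("pixelCoords", function(x) standardGeneric("pixelCoords"))

#' @rdname FeatureMatrix-class
#' @export
setGeneric("featureLabels", function(x) standardGeneric("featureLabels"))

#' @rdname FeatureMatrix-class
#' @export
setGeneric("nPixels", function(x) standardGeneric("nPixels"))

#' @rdname FeatureMatrix-class
#' @export
setGeneric("nFeatures", function(x) standardGeneric("nFeatures"))

#' @rdname CommunityGrid-class
#' @param x,object a `CommunityGrid`
#' @export
setGeneric("communityAssignment",
           function(x) standardGeneric("communityAssignment"))

#' @rdname CommunityGrid-class
#' @export
setGeneric("communityCounts", function(x) standardGeneric("communityCounts"))

#' @rdname CommunityGrid-class
#' @export
setGeneric("nCommunities", function(x) standardGeneric("nCommunities"))

#' @rdname SpectralPartition-class
#' @param x,object a `SpectralPartition`
#' @export
setGeneric("ssGamma", function(x) standardGeneric("ssGamma"))

#' @rdname SpectralPartition-class
#' @export
setGeneric("sdGamma", function(x) standardGeneric("sdGamma"))

#' @rdname SpectralPartition-class
#' @export
setGeneric("ssBeta", function(x) standardGeneric("ssBeta"))

#' @rdname SpectralPartition-class
#' @export
setGeneric("sdBeta", function(x) standardGeneric("sdBeta"))

#' @rdname SpectralPartition-class
#' @export
setGeneric("ssAlpha", function(x) standardGeneric("ssAlpha"))

#' @rdname SpectralPartition-class
#' @export
setGeneric("sdAlpha", function(x) standardGeneric("sdAlpha"))

#' @rdname SpectralPartition-class
#' @export
setGeneric("lcsdGamma", function(x) standardGeneric("lcsdGamma"))

#' @rdname SpectralPartition-class
#' @export
setGeneric("lcsdBeta", function(x) standardGeneric("lcsdBeta"))

#' @rdname SpectralPartition-class
#' @export
setGeneric("fcsdGamma", function(x) standardGeneric("fcsdGamma"))

#' @rdname SpectralPartition-class
#' @export
setGeneric("fcsdBeta", function(x) standardGeneric("fcsdBeta"))

#' @rdname SpectralPartition-class
#' @export
setGeneric("fcsdAlpha", function(x) standardGeneric("fcsdAlpha"))
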