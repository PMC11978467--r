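#' Names of the 107 radiomic features
#'
#' The fixed all-class feature set: 14 shape, 18 first-order, 24 GLCM,
#' 16 GLRLM, 16 GLSZM, 14 GLDM and 5 NGTDM features. Names are stable across
#' runs and prefixed by their feature class.
#'
#' @return Character vector of length 107.
#' @export
radiomic_feature_names <- function() {
  shape <- c("MeshVolume", "VoxelVolume", "SurfaceArea", "SurfaceVolumeRatio",
             "Sphericity", "Maximum3DDiameter", "Maximum2DDiameterSlice",
             "Maximum2DDiameterColumn", "Maximum2DDiameterRow",
             "MajorAxisLength", "MinorAxisLength", "LeastAxisLength",
             "Elongation", "Flatness")
  firstorder <- c("Energy", "TotalEnergy", "Entropy", "Minimum",
                  "Percentile10", "Percentile90", "Maximum", "Mean", "Median",
                  "InterquartileRange", "Range", "MeanAbsoluteDeviation",
                  "RobustMeanAbsoluteDeviation", "RootMeanSquared",
                  "Skewness", "Kurtosis", "Variance", "Uniformity")
  glcm <- c("Autocorrelation", "JointAverage", "ClusterProminence",
            "ClusterShade", "ClusterTendency", "Contrast", "Correlation",
            "DifferenceAverage", "DifferenceEntropy", "DifferenceVariance",
            "JointEnergy", "JointEntropy", "Imc1", "Imc2", "Idm", "Idmn",
            "Id", "Idn", "InverseVariance", "MaximumProbability",
            "SumAverage", "SumEntropy", "SumSquares", "Mcc")
  glrlm <- c("ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
             "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
             "RunLengthNonUniformityNormalized", "RunPercentage",
             "GrayLevelVariance", "RunVariance", "RunEntropy",
             "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
             "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
             "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis")
  glszm <- c("SmallAreaEmphasis", "LargeAreaEmphasis",
             "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
             "SizeZoneNonUniformity", "SizeZoneNonUniformityNormalized",
             "ZonePercentage", "GrayLevelVariance", "ZoneVariance",
             "ZoneEntropy", "LowGrayLevelZoneEmphasis",
             "HighGrayLevelZoneEmphasis", "SmallAreaLowGrayLevelEmphasis",
             "SmallAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
             "LargeAreaHighGrayLevelEmphasis")
  gldm <- c("SmallDependenceEmphasis", "LargeDependenceEmphasis",
            "GrayLevelNonUniformity", "DependenceNonUniformity",
            "DependenceNonUniformityNormalized", "GrayLevelVariance",
            "DependenceVariance", "DependenceEntropy", "LowGrayLevelEmphasis",
            "HighGrayLevelEmphasis", "SmallDependenceLowGrayLevelEmphasis",
            "SmallDependenceHighGrayLevelEmphasis",
            "LargeDependenceLowGrayLevelEmphasis",
            "LargeDependenceHighGrayLevelEmphasis")
  ngtdm <- c("Coarseness", "Contrast", "Busyness", "Complexity", "Strength")
  c(paste0("shape_", shape), paste0("firstorder_", firstorder),
    paste0("glcm_", glcm), paste0("glrlm_", glrlm), paste0("glszm_", glszm),
    paste0("gldm_", gldm), paste0("ngtdm_", ngtdm))
}
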