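#' Run the two-stage synthetic registration study
#'
#' End-to-end experiment on generated paired views with known ground
#' truth, mirroring the two-stage pipeline at desk scale: (1) generate a
#' train / fine-tune / test split of 64 x 64 paired views with 6 px smooth
#' residual deformations; (2) train the displacement network
#' unsupervisedly (MSE + diffusion regularization); (3) transfer the
#' weights and fine-tune semi-supervisedly on the small annotated set;
#' (4) as an ablation, train the semi-supervised network from scratch on
#' the same annotated pairs; (5) evaluate every stage by held-out
#' landmark TRE. The expected qualitative ordering is
#' fine-tuned <= unsupervised <= projective-only (pre-registration), with
#' the from-scratch semi-supervised model trailing the unsupervised one.
#'
#' @param seed master seed; dataset, initialization and training seeds
#'   are derived from it.
#' @param nTrain,nFinetune,nTest split sizes.
#' @param sceneCfg base [SceneConfig] (study conditions).
#' @param netCfg [NetworkConfig] for the displacement network.
#' @param trainCfg [TrainConfig] for the unsupervised phase. Both
#'   fine-tuning arms (warm-started and from-scratch) run the brief
#'   transfer protocol derived from it: a fifth of the epochs at a tenth
#'   of the learning rate (decay from the halfway epoch), the usual
#'   setting for refining a transferred representation on a small
#'   annotated set without overwriting it; `mu` weights the landmark
#'   term.
#' @param residualMagnitude,homographyMagnitude,fieldSpacing view-pair
#'   generation parameters.
#' @param verbose print progress.
#' @return a list with the dataset (`data`), the trained models
#'   (`unsupervised`, `finetuned`, `scratch`), the [TREReport]s
#'   (`trePrereg`, `treUnsupervised`, `treFinetuned`, `treScratch`) and
#'   the percent TRE reduction of the unsupervised stage
#'   (`reductionPct`).
#' @export
runRecoveryExperiment <- function(seed = 1L, nTrain = 200L, nFinetune = 10L,
                                  nTest = 10L, sceneCfg = SceneConfig(),
                                  netCfg = NetworkConfig(),
                                  trainCfg = deskTrainConfig(),
                                  residualMagnitude = 6,
                                  homographyMagnitude = 8,
                                  fieldSpacing = 16, verbose = FALSE) {
  seed <- as.integer(seed)
  ds <- generateDataset(nTrain, nFinetune, nTest, baseCfg = sceneCfg,
                        seed = seed, residualMagnitude = residualMagnitude,
                        homographyMagnitude = homographyMagnitude,
                        fieldSpacing = fieldSpacing)
  trePrereg <- evaluateMethod(identityMethod(), ds@test)

  tc <- trainCfg
  tc@seed <- seed + 2L
  tc@verbose <- isTRUE(verbose)
  model <- buildNetwork(netCfg, seed = seed + 1L)
  unsup <- trainUnsupervised(model, ds@train, tc)
  treUnsup <- evaluateMethod(modelMethod(unsup), ds@test)

  ftCfg <- tc
  ftCfg@learningRate <- tc@learningRate / 10
  ftCfg@epochs <- max(1L, tc@epochs %/% 5L)
  ftCfg@decayStartEpoch <- max(1L, ftCfg@epochs %/% 2L)
  ftCfg@seed <- seed + 3L
  warm <- fineTune(transferWeights(unsup, netCfg), ds@finetune, ftCfg)
  treWarm <- evaluateMethod(modelMethod(warm), ds@test)

  scratchCfg <- ftCfg
  scratchCfg@seed <- seed + 4L
  scratch <- fineTune(buildNetwork(netCfg, seed = seed + 5L), ds@finetune,
                      scratchCfg)
  treScratch <- evaluateMethod(modelMethod(scratch), ds@test)

  list(data = ds,
       unsupervised = unsup, finetuned = warm, scratch = scratch,
       trePrereg = trePrereg, treUnsupervised = treUnsup,
       treFinetuned = treWarm, treScratch = treScratch,
       reductionPct = 100 * (1 - overallTre(treUnsup) / overallTre(trePrereg)))
}
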