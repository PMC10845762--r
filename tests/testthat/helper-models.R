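# Desk-scale study shared by the end-to-end tests: 8 training and 2
# held-out simulated specimen cases at 128 x 128 with a 3 px metal wire,
# the sinogram network trained on 512 patches for 20 epochs and the image
# network on 384 patches for 12 epochs. Built once per test run and
# memoized (training takes a few minutes on one CPU).

.study_cache <- new.env(parent = emptyenv())

study_geometry <- function() scan_geometry()   # 128 px, 360 views, 180 bins

study_wire <- function() {
  metal_wire_spec(center = c(15, -10), radius = 3, attenuation = 50)
}

acceptance_study <- function() {
  if (!is.null(.study_cache$study)) {
    return(.study_cache$study)
  }
  geom <- study_geometry()
  wire <- study_wire()
  train_cases <- generate_dataset(8, geom, seed = 11, wire = wire)
  test_cases <- generate_dataset(2, geom, seed = 9011, wire = wire)
  cfg <- pipeline_config(geometry = geom)

  sp <- sino_training_pairs(train_cases, cfg)
  sino_patches <- extract_patches(sp$inputs, sp$targets, 64, 576, seed = 5)
  unet <- build_modified_unet(net_config("modified_unet", depth = 2,
                                         base_channels = 8), seed = 5)
  unet_state <- train_model(
    unet, sino_patches,
    desk_train_config("sino", n_train_patches = 512, n_val_patches = 64,
                      epochs = 20, seed = 5))

  ip <- image_training_pairs(train_cases, cfg, unet_state$model)
  img_patches <- extract_patches(ip$inputs, ip$targets, 48, 432, seed = 6)
  resu <- build_modified_resunet(net_config("modified_resunet", depth = 2,
                                            base_channels = 8), seed = 6)
  resu_state <- train_model(
    resu, img_patches,
    desk_train_config("image", n_train_patches = 384, n_val_patches = 48,
                      epochs = 12, seed = 6))

  cfg$sino_model <- unet_state$model
  cfg$image_model <- resu_state$model
  .study_cache$study <- list(geom = geom, wire = wire,
                             train_cases = train_cases,
                             test_cases = test_cases, config = cfg,
                             unet_state = unet_state,
                             resu_state = resu_state)
  .study_cache$study
}
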