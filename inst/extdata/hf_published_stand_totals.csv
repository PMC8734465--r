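scientific_name,n_individuals,basal_area_m2,biomass_Mg
Acer pensylvanicum,339,0.59,1.13
Acer rubrum,9723,253.54,1182.86
Acer saccharum,1,3.12e-03,0.02
Alnus incana,479,0.68,0.60
Amelanchier laevis,572,0.35,0.61
Aronia melanocarpa,413,0.07,0.10
Betula alleghaniensis,4059,36.96,207.73
Betula lenta,1430,21.14,124.04
Betula papyrifera,537,14.80,72.76
Betula populifolia,108,1.49,7.18
Castanea dentata,732,1.12,4.35
Crataegus spp.,180,0.14,0.27
Fagus grandifolia,3802,20.93,138.58
Frangula alnus,3,7.42e-04,4.90e-04
Fraxinus americana,186,3.84,23.73
Fraxinus nigra,34,0.17,0.82
Hamamelis virginiana,1931,3.10,5.77
Ilex laevigata,2,1.39e-03,2.76e-03
Ilex mucronata,598,0.64,0.58
Ilex verticillata,9874,3.62,6.15
Juniperus communis,1,4.52e-04,4.20e-04
Kalmia latifolia,3914,3.27,7.64
Lindera benzoin,66,0.02,0.04
Lyonia ligustrina,1178,0.41,2.04
Nyssa sylvatica,180,2.63,11.25
Ostrya virginiana,24,0.06,0.19
Picea abies,900,24.43,93.11
Picea rubens,101,3.61,15.15
Pinus resinosa,790,67.23,330.28
Pinus strobus,2126,155.68,724.64
Populus grandidentata,2,0.03,0.14
Populus tremuloides,1,0.01,0.05
Prunus pensylvanica,11,0.05,0.98
Prunus serotina,250,5.48,34.85
Quercus alba,38,1.89,14.53
Quercus rubra,3896,334.99,2627.07
Quercus velutina,206,19.28,164.46
Rhododendron prinophyllum,127,0.05,0.25
Salix spp.,2,1.59e-04,1.50e-03
Sambucus racemosa,2,5.65e-04,4.03e-03
Sorbus americana,66,0.26,2.78
Toxicodendron radicans,1,1.13e-04,1.05e-04
Toxicodendron vernix,521,0.32,0.38
Tsuga canadensis,22880,491.07,2138.00
Ulmus americana,1,2.84e-04,3.85e-04
Vaccinium corymbosum,3531,2.39,9.58
Viburnum acerifolium,39,0.01,0.07
Viburnum dentatum,325,0.08,0.52
Viburnum lantanoides,75,0.01,0.01
Viburnum nudum,1182,0.44,2.27
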