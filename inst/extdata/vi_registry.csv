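name,formula
NDVI,(nir - red)/(nir + red)
GNDVI,(nir - green)/(nir + green)
NDRE,(nir - red_edge)/(nir + red_edge)
RVI,nir/red
GRVI,nir/green
RERVI,nir/red_edge
CIgreen,nir/green - 1
CIrededge,nir/red_edge - 1
DVI,nir - red
GDVI,nir - green
RDVI,(nir - red)/sqrt(nir + red)
SAVI,1.5*(nir - red)/(nir + red + 0.5)
OSAVI,(nir - red)/(nir + red + 0.16)
MSAVI,(2*nir + 1 - sqrt((2*nir + 1)^2 - 8*(nir - red)))/2
EVI2,2.5*(nir - red)/(nir + 2.4*red + 1)
MTCI,(nir - red_edge)/(red_edge - red)
NGRDI,(green - red)/(green + red)
MSR,(nir/red - 1)/sqrt(nir/red + 1)
WDRVI,(0.12*nir - red)/(0.12*nir + red)
TVI,0.5*(120*(nir - green) - 200*(red - green))
MCARI,((red_edge - red) - 0.2*(red_edge - green))*(red_edge/red)
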