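experiment,feature,variant,true_class,pred_meningioma,pred_glioma,pred_pituitary,sensitivity_pct
augmentation,histogram,without,meningioma,428,36,244,60.5
augmentation,histogram,without,glioma,37,1262,127,88.5
augmentation,histogram,without,pituitary,240,192,498,53.5
augmentation,histogram,with,meningioma,524,63,121,74.0
augmentation,histogram,with,glioma,46,1291,89,90.5
augmentation,histogram,with,pituitary,134,91,705,75.8
augmentation,glcm_element,without,meningioma,491,46,171,69.4
augmentation,glcm_element,without,glioma,31,1293,102,90.7
augmentation,glcm_element,without,pituitary,173,146,611,65.7
augmentation,glcm_element,with,meningioma,555,53,100,78.4
augmentation,glcm_element,with,glioma,51,1306,69,91.6
augmentation,glcm_element,with,pituitary,122,73,735,79.0
augmentation,bow,without,meningioma,532,35,141,75.1
augmentation,bow,without,glioma,29,1330,67,93.3
augmentation,bow,without,pituitary,125,108,697,74.9
augmentation,bow,with,meningioma,571,57,80,80.6
augmentation,bow,with,glioma,44,1326,56,93.0
augmentation,bow,with,pituitary,75,54,801,86.1
partition,histogram,without,meningioma,518,64,126,73.2
partition,histogram,without,glioma,48,1292,86,90.6
partition,histogram,without,pituitary,134,81,715,76.9
partition,histogram,with,meningioma,562,31,115,79.4
partition,histogram,with,glioma,38,1363,25,95.6
partition,histogram,with,pituitary,130,42,758,81.5
partition,glcm_element,without,meningioma,556,45,107,78.5
partition,glcm_element,without,glioma,35,1328,63,93.1
partition,glcm_element,without,pituitary,99,73,758,81.5
partition,glcm_element,with,meningioma,582,26,100,82.2
partition,glcm_element,with,glioma,25,1376,25,96.5
partition,glcm_element,with,pituitary,99,40,791,85.1
partition,bow,without,meningioma,569,62,77,80.4
partition,bow,without,glioma,45,1318,63,92.4
partition,bow,without,pituitary,75,54,801,86.1
partition,bow,with,meningioma,609,23,76,86.0
partition,bow,with,glioma,27,1374,25,96.4
partition,bow,with,pituitary,80,38,812,87.3
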